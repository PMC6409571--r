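---
title: "Surveying tRNA gene clusters in virus genomes"
author: "trnaclusterscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying tRNA gene clusters in virus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaclusterscan)
```

## The problem

Viruses depend on the host translation machinery, yet many double-stranded
DNA phages carry their own tRNA genes, and in some genomes dozens of them
sit together in dense clusters. Surveying such clusters across a cohort of
genomes raises a chain of concrete questions this package answers with
tested code: where are the clusters, which genomes share the same cluster
architecture, which codons do a cluster's tRNAs decode, and do those codons
coincide with the codons the genome — or a highly expressed gene such as
the major capsid protein (MCP) — prefers?

The package does **not** predict tRNA genes. Prediction belongs to upstream
tools (ARAGORN, tRNAscan-SE); their tabular or GFF3 output is what the
readers in `read_trna_annotations()` consume.

## The cluster model

A *tRNA gene cluster* is a run of consecutive tRNA genes whose density —
gene count per kb of spanned sequence — meets a threshold. The survey
definition, applied throughout:

* at least `min_genes = 15` member genes, and
* density `n / ((span_end - span_start)/1000) >= min_density = 2` tRNA/kb,

with the span measured from the first member's start to the last member's
end. Both comparisons are inclusive, so a run of 15 genes spanning exactly
7,500 bp is a cluster. Measuring the span over the members themselves (not
midpoints, not a padded window) makes a cluster's density an intrinsic
property of its member genes.

Density thresholds alone do not determine a unique decomposition of a gene
run into clusters, so `detect_clusters()` fixes one deterministically:

1. every window of consecutive genes satisfying both thresholds is a
   *qualifying* window;
2. a qualifying window is *maximal* when no strictly containing window also
   qualifies;
3. maximal windows that do not overlap are all reported. When two maximal
   windows overlap, their union must have failed the density test (a
   qualifying union would contain both, contradicting maximality), so the
   window with more genes is reported first (tie: leftmost) and the genes
   on either side are re-scanned.

This rule is order-independent, reduces to the obvious answer on
well-separated dense runs, and is cross-checked in the test suite against
an independent brute-force enumerator on hundreds of random instances.
Strand is ignored for clustering — clusters routinely mix strands and the
definition never conditions on it. Circular genomes are handled opt-in by
virtually doubling the gene list; NCBI viral FASTA does not record
topology, so linear is the default.

## Isotype synteny groups

Each cluster's *signature* is the string of member isotypes (single-letter
amino-acid code, plus O = pyrrolysine, U = selenocysteine, X =
undetermined) in genomic order. Since no reading strand is privileged, a
signature and its reversal describe the same arrangement;
`canonicalize_signature()` keeps the lexicographically smaller of the two
(this orientation equivalence can be switched off). Grouping
(`group_clusters()`) is by exact canonical-signature match: groups are
numbered G1, G2, ... by decreasing size, ties broken lexicographically, and
size-1 groups are singletons.

Near-membership — e.g. a cluster differing from a group only by a terminal
deletion of a few genes — is deliberately *reported*, not merged:
`signature_distance()` gives the Levenshtein distance between canonical
signatures (minimized over the two orientation pairings; it is a metric on
orientation classes), and `report_near_matches()` lists singletons within a
caller-chosen distance of each group. Exact grouping keeps the partition
unambiguous; any tolerance would need an arbitrary cut-off, so the cut-off
is exposed as a report parameter instead. X never matches a determined
isotype.

## Codon usage and preferred-codon matching

Relative synonymous codon usage for codon $c$ in synonymous family $F$:

$$\mathrm{RSCU}(c) = \frac{x_c \, |F|}{\sum_{c' \in F} x_{c'}}$$

where $x_c$ is the observed count. RSCU 1 means no bias; values above 1
mark codons used more than expected under uniform synonymous usage.
Families with zero total count are *undefined* and reported as `NA`, never
as 0 — a codon that was never observable is not evidence of avoidance. Stop
codons are excluded; Met and Trp (single-codon families) are 1 whenever
observed. Only the standard genetic code is supported.

A cluster's codon inventory (`cluster_codon_pattern()`) maps each member
anticodon to its codon by exact Watson–Crick reverse complement — wobble
decoding is out of scope, so the inventory is a conservative lower bound on
decodable codons. `match_preferred_codons()` then computes
$|P \cap S| / |P|$ where $P$ is the set of sense codons with RSCU
strictly $> 1$ in the target profile and $S$ the set of codons the cluster
supplies. Matching is by *sets*, not copy numbers: the question is which
preferred codons are covered at all, while dosage remains available in the
copy-number matrix (`codon_pattern_matrix()`). Pyrrolysine and
selenocysteine tRNAs decode stop codons and therefore count toward isotypes
but can never match a sense codon. Whole-genome profiles include every CDS,
the MCP among them.

## Cohort statistics

`summarize_genomes()` tabulates per-genome tRNA counts, clustering
fractions and distinct determined isotypes among clustered genes (X
excluded). Choices the survey literature leaves open are fixed and
documented here:

* **Spearman correlation** (`spearman_correlation()`): average ranks for
  ties, p-value by the asymptotic t-approximation. Constant input is `NA`.
* **Two-group comparison** (`compare_groups()`): two-sided Mann–Whitney U
  with normal approximation, continuity and tie correction; "non-parametric
  test" is otherwise underspecified and Mann–Whitney is the standard
  two-group location test. The p-value needs at least 3 observations per
  group. Quantiles (medians, IQRs) use linear interpolation, R's default
  type 7.
* **Lifestyle** (`classify_lifestyle()`): temperate iff any CDS product
  matches "integrase" (case-insensitive), the annotation-keyword procedure
  the survey itself uses; serine/tyrosine subtypes are reported when named.
  Excisionase or recombinase keywords are not used. No CDS annotations at
  all means `unknown`, not virulent.

No multiple-testing correction is applied anywhere.

## The synthetic-data generator

`generate_genome()` produces genomes the pipeline can be tested on without
any download, with a recorded ground truth. What it emulates: genome
lengths from a few kb up to ~1.2 Mb, background GC around a configurable
target (default 0.44, a typical phage-cohort median), clusters of 15–37
genes at 2–10 tRNA/kb, loose tRNA genes, and CDSs with a controllable
synonymous-codon bias (designated codons weighted $w \ge 1$ within their
family; $w = 1$ is exactly uniform usage, and a designated codon in a
family of size $k$ has expected RSCU $kw/(w + k - 1)$).

Numerical choices:

* tRNA genes are fixed-length 72 bp coordinate intervals — typical tRNA
  size — uniformly spaced over a span of `n / target_density` kb, so the
  achieved density equals the target up to 1-bp coordinate rounding. They
  are *not* realistic tRNA sequences: the pipeline consumes annotations and
  never re-predicts.
* **Separation.** Adjacent planted features are separated by gaps sized so
  that a window crossing the gap can never reach the detection threshold:
  for neighbors with $n_A, n_B$ genes over spans $s_A, s_B$, the gap
  exceeds $(n_A + n_B)/d \cdot 1000 - s_A - s_B$ bp (8 kb floor, $d$ = 2
  tRNA/kb by default). A naive fixed gap is not enough — a dense 37-gene
  cluster next to a 15-gene cluster can pull a gap-crossing window above
  2 tRNA/kb, and the detector would then (correctly, under its maximality
  rule) merge the plants. Pairwise-safe gaps compose across multiple gaps
  because each planted feature's own density is at least the threshold.
  This is what makes planted truth exactly recoverable, a property the
  suite checks over 100 seeds.
* All randomness flows from the spec's mandatory seed through a private RNG
  stream; the caller's global RNG state is untouched, and identical specs
  give byte-identical output.

What the generator does **not** emulate — and hence what green tests do not
show about real data: overlapping or nested gene annotations, predictor
error modes (missed genes, wrong anticodons), strand mixtures within
clusters, phylogenetic correlation between genomes, and compositional
heterogeneity along the genome. Results on real cohorts depend on upstream
annotation quality in ways synthetic tests cannot certify.

## Problem sizes in the shipped suite

The test suite runs the detector against a brute-force oracle on 500 random
instances of up to 40 genes, recovers planted clusters over 100 seeded
genomes of 90 kb, and checks designated-bias recovery on 100 CDSs of
10,000 codons — sizes chosen so the whole suite completes in about a
minute while still exercising every decision boundary (15 genes, 2 tRNA/kb,
RSCU = 1) exactly.

## Known limitations

* Only the standard genetic code; genomes using alternative codes would
  need a different family table.
* Exact anticodon–codon pairing understates decoding capacity (no wobble).
* Circular-mode handling reports origin-spanning clusters but has seen far
  less adversarial testing than linear mode.
* `find_mcp()` trusts product annotations; unannotated or creatively named
  capsid genes are missed.
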