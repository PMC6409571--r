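Package: trnaclusterscan
Title: Detection and Characterization of tRNA Gene Clusters in Virus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying transfer RNA (tRNA) gene clusters in viral
    genomes, chiefly bacteriophages. Reads genome sequences and tRNA/CDS
    annotations from standard formats (FASTA, GFF3, tRNAscan-SE tabular),
    detects tRNA gene clusters as maximal dense runs of consecutive tRNA
    genes (default: at least 15 genes at a density of at least 2 tRNA genes
    per kilobase), classifies clusters into groups by their isotype synteny
    signature, computes relative synonymous codon usage (RSCU) profiles and
    the fraction of preferred codons a cluster supplies for a target gene or
    whole genome, and produces cohort-level summary statistics. A synthetic
    genome generator with planted clusters and controllable codon bias makes
    every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
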