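# Run code under a local RNG seeded from `seed`, leaving the caller's
# global RNG state untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Plan for one planted tRNA gene cluster
#'
#' @param n_genes Number of member genes (>= 15 for a true cluster; smaller
#'   values are allowed as negative controls).
#' @param target_density Target density in tRNA genes per kb; the planted
#'   span is solved from the density definition as
#'   `n_genes / target_density` kb.
#' @param signature Isotype string of length `n_genes`, or `"random"` to
#'   draw isotypes uniformly from the 20 standard amino acids.
#' @param anticodons Character vector of per-gene anticodons consistent with
#'   the isotypes, or `"random"` to draw a synonymous codon per isotype and
#'   reverse-complement it.
#' @return A list of class `cluster_plan`.
#' @export
cluster_plan <- function(n_genes = 15L, target_density = 2.0,
                         signature = "random", anticodons = "random") {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L, target_density > 0)
  if (!identical(signature, "random") && nchar(signature) != n_genes) {
    stop("signature length must equal n_genes")
  }
  structure(list(n_genes = n_genes, target_density = target_density,
                 signature = signature, anticodons = anticodons),
            class = "cluster_plan")
}

#' Parameterization of a synthetic genome
#'
#' Describes one synthetic virus genome: background length and GC content,
#' planted tRNA gene clusters, loose (unclustered) tRNA genes, and CDSs with
#' a controllable synonymous-codon bias. The defaults mirror the survey's
#' observed ranges: genomes of a few kb up to ~1.2 Mb, clusters of 15-37
#' genes at ~2-10 tRNA/kb, cohort median GC around 0.44.
#'
#' @param genome_length Genome length in bp.
#' @param gc_target Background GC fraction (default 0.44, a typical phage
#'   cohort median).
#' @param clusters List of [cluster_plan()] objects.
#' @param n_loose_trna Number of unclustered tRNA genes; these are placed
#'   pairwise farther apart than any qualifying cluster span, so they can
#'   never join a cluster under the default thresholds.
#' @param n_cds Number of planted CDSs.
#' @param cds_length_codons Codons per planted CDS (default 300).
#' @param designated Designated preferred codon set for CDS bias.
#' @param bias_weight Within-family sampling weight `w >= 1` for designated
#'   codons (1 = uniform synonymous usage).
#' @param mcp_flag Annotate the first CDS as "major capsid protein".
#' @param sep_density Density threshold (tRNA/kb) the planted layout is
#'   guarded against: inter-feature gaps are sized so that no window of
#'   tRNA genes crossing a gap can reach this density (default 2.0, the
#'   survey threshold), with an 8 kb floor. This is what makes the planted
#'   truth exactly recoverable by [detect_clusters()].
#' @param seed Mandatory integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_length,
                                  gc_target = 0.44,
                                  clusters = list(),
                                  n_loose_trna = 0L,
                                  n_cds = 0L,
                                  cds_length_codons = 300L,
                                  designated = character(),
                                  bias_weight = 1,
                                  mcp_flag = FALSE,
                                  sep_density = 2.0,
                                  seed) {
  stopifnot(genome_length > 0, gc_target >= 0, gc_target <= 1,
            bias_weight >= 1)
  if (missing(seed)) stop("a seed is required")
  for (cp in clusters) {
    if (!inherits(cp, "cluster_plan")) stop("clusters must be cluster_plan objects")
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_target = gc_target, clusters = clusters,
                 n_loose_trna = as.integer(n_loose_trna),
                 n_cds = as.integer(n_cds),
                 cds_length_codons = as.integer(cds_length_codons),
                 designated = designated, bias_weight = bias_weight,
                 mcp_flag = mcp_flag, sep_density = sep_density,
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

TRNA_GENE_LENGTH <- 72L   # typical tRNA gene size; planted genes are
                          # coordinate intervals, not realistic sequences
FEATURE_GAP <- 8000L      # floor on inter-feature gaps, > (15 genes /
                          # 2 tRNA/kb) = 7.5 kb

# Gap between two adjacent planted features (n genes over span bp each)
# large enough that any window crossing the gap falls below
# `sep_density` tRNA/kb: (nA + nB) / (spanA + gap + spanB) < sep_density.
# Pairwise-safe gaps compose across multiple gaps because every planted
# feature's own density is at least sep_density.
separation_gap <- function(nA, spanA, nB, spanB, sep_density) {
  need <- ceiling((nA + nB) / sep_density * 1000) - spanA - spanB + 1000L
  max(FEATURE_GAP, as.integer(need))
}

#' Generate a synthetic genome with planted tRNA clusters and CDSs
#'
#' The background sequence is i.i.d. with P(G or C) = `gc_target`. Each
#' cluster plan is laid out over a span of `n_genes / target_density` kb
#' with uniformly spaced 72-bp tRNA genes, so the achieved density equals
#' the target up to integer rounding of coordinates. Adjacent planted
#' features (clusters, loose tRNAs) are separated by gaps sized so that no
#' run of tRNA genes crossing a gap can reach `sep_density` tRNA/kb (with
#' an 8 kb floor), which makes the planted truth exactly recoverable by
#' [detect_clusters()] at that threshold. Infeasible packing is an error
#' before any output.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param genome_id Identifier for the generated genome.
#' @return A list with `genome` (one-row genome table carrying the sequence
#'   attribute), `trna` (annotation table, internal coordinates), `cds`
#'   (CDS table), and `truth` (one row per planted tRNA gene with its
#'   planted cluster assignment, `cluster_id` 0 = loose).
#' @export
generate_genome <- function(spec, genome_id = "synth1") {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  L <- spec$genome_length
  # ---- feasibility before any randomness ----
  spans <- vapply(spec$clusters, function(cp) {
    span <- as.integer(round(cp$n_genes / cp$target_density * 1000))
    if (span < cp$n_genes * TRNA_GENE_LENGTH) {
      stop("cluster plan infeasible: ", cp$n_genes, " genes of ",
           TRNA_GENE_LENGTH, " bp cannot fit a span of ", span, " bp")
    }
    span
  }, integer(1))
  n_feat <- c(vapply(spec$clusters, function(cp) cp$n_genes, integer(1)),
              rep(1L, spec$n_loose_trna))
  span_feat <- c(spans, rep(TRNA_GENE_LENGTH, spec$n_loose_trna))
  gaps <- if (length(n_feat) > 1L) {
    vapply(seq_len(length(n_feat) - 1L), function(i) {
      separation_gap(n_feat[i], span_feat[i], n_feat[i + 1L],
                     span_feat[i + 1L], spec$sep_density)
    }, numeric(1))
  } else numeric(0)
  cds_len_bp <- spec$n_cds * (spec$cds_length_codons * 3L + 200L)
  need <- 2000 + sum(span_feat) + sum(gaps) +
    (if (spec$n_cds > 0L) FEATURE_GAP + cds_len_bp else 0) + 100
  if (need > L) {
    stop("planted features need ", need, " bp but genome_length is ", L)
  }

  with_local_seed(spec$seed, {
    trna_rows <- list()
    truth_rows <- list()
    feat_i <- 0L
    cursor <- 2000L
    advance <- function(cursor, span) {
      # move past this feature plus its trailing separation gap
      cursor + span +
        (if (feat_i < length(n_feat)) gaps[feat_i] else FEATURE_GAP)
    }
    for (k in seq_along(spec$clusters)) {
      cp <- spec$clusters[[k]]
      span <- spans[k]
      n <- cp$n_genes
      feat_i <- feat_i + 1L
      starts <- if (n == 1L) cursor else
        as.integer(round(seq(cursor, cursor + span - TRNA_GENE_LENGTH,
                             length.out = n)))
      iso <- if (identical(cp$signature, "random")) {
        sample(STANDARD_AA, n, replace = TRUE)
      } else strsplit(cp$signature, "")[[1]]
      anti <- if (identical(cp$anticodons, "random")) {
        vapply(iso, random_anticodon_for, character(1))
      } else cp$anticodons
      trna_rows[[length(trna_rows) + 1L]] <- data.frame(
        genome_id = genome_id, start = starts,
        end = starts + TRNA_GENE_LENGTH,
        strand = "+", isotype = iso, anticodon = anti,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        genome_id = genome_id, cluster_id = k, start = starts,
        end = starts + TRNA_GENE_LENGTH, isotype = iso,
        stringsAsFactors = FALSE)
      cursor <- advance(cursor, span)
    }
    if (spec$n_loose_trna > 0L) {
      for (k in seq_len(spec$n_loose_trna)) {
        feat_i <- feat_i + 1L
        iso <- sample(STANDARD_AA, 1L)
        trna_rows[[length(trna_rows) + 1L]] <- data.frame(
          genome_id = genome_id, start = cursor,
          end = cursor + TRNA_GENE_LENGTH, strand = "+", isotype = iso,
          anticodon = random_anticodon_for(iso), stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          genome_id = genome_id, cluster_id = 0L, start = cursor,
          end = cursor + TRNA_GENE_LENGTH, isotype = iso,
          stringsAsFactors = FALSE)
        cursor <- advance(cursor, TRNA_GENE_LENGTH)
      }
    }

    cds_rows <- list()
    if (spec$n_cds > 0L) {
      for (k in seq_len(spec$n_cds)) {
        cdsr <- generate_biased_cds(spec$cds_length_codons,
                                    designated = spec$designated,
                                    w = spec$bias_weight)
        len <- nchar(cdsr$sequence)
        cds_rows[[k]] <- data.frame(
          genome_id = genome_id,
          cds_id = sprintf("%s_cds%03d", genome_id, k),
          start = cursor, end = cursor + len, strand = "+",
          product = if (spec$mcp_flag && k == 1L) "major capsid protein"
                    else "hypothetical protein",
          sequence = cdsr$sequence, stringsAsFactors = FALSE)
        cursor <- cursor + len + 200L
      }
    }

    p_gc <- spec$gc_target
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2,
                             (1 - p_gc) / 2))
    for (r in cds_rows) {
      bases[(r$start + 1L):r$end] <- strsplit(r$sequence, "")[[1]]
    }
    seq_chr <- paste(bases, collapse = "")
    seqs <- Biostrings::DNAStringSet(seq_chr)
    names(seqs) <- genome_id
    freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    genome <- data.frame(genome_id = genome_id, length_bp = L,
                         gc_fraction = (freq[, "G"] + freq[, "C"]) / sum(freq),
                         circular = FALSE, stringsAsFactors = FALSE)
    attr(genome, "sequences") <- seqs

    bind <- function(x, template) if (length(x)) do.call(rbind, x)
                                  else template
    trna <- bind(trna_rows, empty_trna_table())
    cds <- bind(cds_rows, data.frame(
      genome_id = character(), cds_id = character(), start = integer(),
      end = integer(), strand = character(), product = character(),
      sequence = character(), stringsAsFactors = FALSE))
    truth <- bind(truth_rows, data.frame(
      genome_id = character(), cluster_id = integer(), start = integer(),
      end = integer(), isotype = character(), stringsAsFactors = FALSE))
    trna <- trna[order(trna$start), , drop = FALSE]
    rownames(trna) <- rownames(cds) <- rownames(truth) <- NULL
    list(genome = genome, trna = trna, cds = cds, truth = truth)
  })
}

# Draw an anticodon consistent with an isotype: pick a synonymous codon of
# the amino acid and reverse-complement it. Pyl decodes TAG, Sec TGA;
# undetermined isotypes get no anticodon.
random_anticodon_for <- function(isotype) {
  if (isotype == "X") return(NA_character_)
  codon <- if (isotype == "O") "TAG"
           else if (isotype == "U") "TGA"
           else {
             fam <- codon_families()[[isotype]]
             fam[sample.int(length(fam), 1L)]
           }
  anticodon_to_codon(codon)  # reverse complement is an involution
}

#' Generate a CDS with a designated synonymous-codon bias
#'
#' Interior codons are drawn by first picking an amino-acid family uniformly
#' among the 20 standard families, then a codon within the family with
#' designated members weighted `w` and the rest 1, so `w = 1` gives uniform
#' synonymous usage (expected RSCU 1 for every codon) and a designated codon
#' in a family of size k has expected RSCU `k * w / (w + k - 1)`. The
#' sequence starts with ATG and ends with a random stop codon.
#'
#' @param length_codons Total codon count including start and stop (>= 3).
#' @param designated Character vector of designated sense codons.
#' @param w Bias weight >= 1.
#' @param seed Optional integer seed for a private RNG stream.
#' @return A one-row CDS data.frame (`cds_id`, `product`, `sequence`).
#' @export
generate_biased_cds <- function(length_codons, designated = character(),
                                w = 1, seed = NULL) {
  length_codons <- as.integer(length_codons)
  if (length_codons < 3L) stop("length_codons must be at least 3")
  stopifnot(w >= 1)
  bad <- setdiff(designated, SENSE_CODONS())
  if (length(bad)) {
    stop("designated codons must be sense codons: ",
         paste(bad, collapse = ", "))
  }
  draw <- function() {
    fams <- codon_families()
    n_int <- length_codons - 2L
    fam_idx <- sample.int(length(fams), n_int, replace = TRUE)
    interior <- character(n_int)
    for (fi in unique(fam_idx)) {
      cods <- fams[[fi]]
      wts <- ifelse(cods %in% designated, w, 1)
      sel <- fam_idx == fi
      interior[sel] <- sample(cods, sum(sel), replace = TRUE,
                              prob = wts / sum(wts))
    }
    stop_codon <- STOP_CODONS()[sample.int(3L, 1L)]
    paste(c("ATG", interior, stop_codon), collapse = "")
  }
  seq_chr <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  data.frame(cds_id = "biased_cds", product = "synthetic biased CDS",
             sequence = seq_chr, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of genome lengths and tRNA counts
#'
#' Genome lengths are drawn from `length_distribution`; per-genome tRNA
#' counts are `round(slope * length + noise)` clipped at zero, giving the
#' length/tRNA-count association the survey's correlation machinery is
#' exercised on.
#'
#' @param n_genomes Number of genomes (>= 3).
#' @param length_distribution A function `n -> lengths in bp`; the default
#'   draws log-normal lengths clipped to the 5 kb - 1.2 Mb range the survey
#'   covers.
#' @param trna_length_slope Expected tRNA genes per bp (e.g. 2e-4 gives ~20
#'   genes at 100 kb).
#' @param noise_sd Standard deviation of additive Gaussian noise on counts.
#' @param seed Integer seed.
#' @return A data.frame with `genome_id`, `length_bp`, `n_trna`.
#' @export
generate_cohort <- function(n_genomes,
                            length_distribution = NULL,
                            trna_length_slope = 2e-4,
                            noise_sd = 0,
                            seed) {
  n_genomes <- as.integer(n_genomes)
  if (n_genomes < 3L) stop("need at least 3 genomes")
  if (is.null(length_distribution)) {
    length_distribution <- function(n) {
      pmin(pmax(round(rlnorm(n, meanlog = log(5e4), sdlog = 1)), 5e3), 1.2e6)
    }
  }
  with_local_seed(seed, {
    len <- length_distribution(n_genomes)
    counts <- pmax(0, round(trna_length_slope * len +
                              rnorm(n_genomes, 0, noise_sd)))
    data.frame(genome_id = sprintf("synth%04d", seq_len(n_genomes)),
               length_bp = as.numeric(len), n_trna = as.integer(counts),
               stringsAsFactors = FALSE)
  })
}
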