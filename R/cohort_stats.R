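#' Per-genome survey summary
#'
#' One row per genome: tRNA gene counts, clustering summary, distinct
#' determined isotypes among clustered genes (X excluded), and lifestyle
#' call from the CDS annotations (see [classify_lifestyle()]).
#'
#' @param genomes Genome table ([read_genome_fasta()]).
#' @param genes tRNA gene table over all genomes.
#' @param clusters Concatenated [detect_clusters()] output.
#' @param cds Optional CDS table over all genomes; when NULL every genome's
#'   lifestyle is `unknown`.
#' @return A data.frame with columns `genome_id`, `length_bp`,
#'   `gc_fraction`, `n_trna`, `n_clustered`, `n_clusters`,
#'   `fraction_clustered` (NA when `n_trna` is 0), `n_isotypes`,
#'   `lifestyle`.
#' @export
summarize_genomes <- function(genomes, genes, clusters, cds = NULL) {
  bad <- setdiff(clusters$genome_id, genomes$genome_id)
  if (length(bad)) {
    stop("cluster(s) reference unknown genome(s): ",
         paste(unique(bad), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(genomes)), function(i) {
    gid <- genomes$genome_id[i]
    g <- genes[genes$genome_id == gid, , drop = FALSE]
    cl <- clusters[clusters$genome_id == gid, , drop = FALSE]
    n_trna <- nrow(g)
    n_clustered <- sum(cl$n_genes)
    clustered_iso <- unlist(lapply(cl$members, function(m) m$isotype))
    determined <- setdiff(unique(clustered_iso), "X")
    lifestyle <- if (is.null(cds)) "unknown" else {
      classify_lifestyle(cds[!is.na(cds$genome_id) &
                               cds$genome_id == gid, , drop = FALSE])$lifestyle
    }
    data.frame(
      genome_id = gid,
      length_bp = genomes$length_bp[i],
      gc_fraction = genomes$gc_fraction[i],
      n_trna = n_trna,
      n_clustered = n_clustered,
      n_clusters = nrow(cl),
      fraction_clustered = if (n_trna > 0) n_clustered / n_trna else NA_real_,
      n_isotypes = length(determined),
      lifestyle = lifestyle,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation (the asymptotic test, suitable for the
#' cohort sizes this survey works at). A constant vector has no defined
#' rank correlation and yields NA with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_correlation(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; rank correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Two-group nonparametric comparison
#'
#' Two-sided Mann-Whitney U test (normal approximation with continuity and
#' tie correction) plus medians and interquartile ranges. Quantiles use
#' linear interpolation (R's default type 7). The reported `statistic` is
#' U for group A: the number of (a, b) pairs with a > b (ties count 1/2).
#' The p-value is NA when either group has fewer than 3 observations.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param label_a,label_b Group labels for the report.
#' @return A one-row data.frame: labels, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `iqr_lo_a`, `iqr_hi_a`, `iqr_lo_b`, `iqr_hi_b`,
#'   `statistic`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b,
                           label_a = "a", label_b = "b") {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("empty group")
  }
  qa <- quantile(values_a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qb <- quantile(values_b, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
  p <- if (min(length(values_a), length(values_b)) >= 3L) wt$p.value
       else NA_real_
  data.frame(
    group_a = label_a, group_b = label_b,
    n_a = length(values_a), n_b = length(values_b),
    median_a = qa[2], median_b = qb[2],
    iqr_lo_a = qa[1], iqr_hi_a = qa[3],
    iqr_lo_b = qb[1], iqr_hi_b = qb[3],
    statistic = unname(wt$statistic),
    p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Lifestyle call from CDS annotations
#'
#' A phage is called temperate when at least one CDS product matches
#' "integrase" (case-insensitive) -- the marker of host-genome integration
#' -- and virulent otherwise; with no CDS annotations at all the call is
#' unknown. When an integrase product also names a serine or tyrosine
#' recombinase family, the subtype is reported.
#'
#' @param cds CDS table for one genome (may have zero rows).
#' @return A list with `lifestyle` (`"virulent"`, `"temperate"`,
#'   `"unknown"`) and `integrase_subtype` (`"serine"`, `"tyrosine"` or NA).
#' @export
classify_lifestyle <- function(cds) {
  if (is.null(cds) || nrow(cds) == 0L) {
    return(list(lifestyle = "unknown", integrase_subtype = NA_character_))
  }
  prod <- cds$product
  hit <- !is.na(prod) & grepl("integrase", prod, ignore.case = TRUE)
  if (!any(hit)) {
    return(list(lifestyle = "virulent", integrase_subtype = NA_character_))
  }
  hits <- prod[hit]
  subtype <- if (any(grepl("serine", hits, ignore.case = TRUE))) "serine"
             else if (any(grepl("tyrosine", hits, ignore.case = TRUE)))
               "tyrosine"
             else NA_character_
  list(lifestyle = "temperate", integrase_subtype = subtype)
}

#' Per-family cohort table
#'
#' For each viral family: how many genomes carry at least one tRNA gene out
#' of the family total, the genome length range, the tRNA gene count range
#' among tRNA-carrying genomes, and the average GC content in percent.
#' Genomes without a family assignment are binned as "unclassified".
#'
#' @param summaries Output of [summarize_genomes()].
#' @param metadata Data.frame mapping `genome_id` to `family`.
#' @return A data.frame with one row per family.
#' @export
summarize_families <- function(summaries, metadata) {
  fam <- metadata$family[match(summaries$genome_id, metadata$genome_id)]
  fam[is.na(fam) | fam == ""] <- "unclassified"
  rows <- lapply(split(seq_len(nrow(summaries)), fam), function(ix) {
    s <- summaries[ix, , drop = FALSE]
    with_trna <- s[s$n_trna > 0, , drop = FALSE]
    data.frame(
      family = fam[ix[1]],
      n_genomes = nrow(s),
      n_with_trna = nrow(with_trna),
      genomes_with_trna = sprintf("%d/%d", nrow(with_trna), nrow(s)),
      length_min_bp = min(s$length_bp),
      length_max_bp = max(s$length_bp),
      trna_range = if (nrow(with_trna))
        sprintf("%d-%d", min(with_trna$n_trna), max(with_trna$n_trna))
      else "",
      avg_gc_percent = round(mean(s$gc_fraction) * 100, 2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
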