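#' Cluster scan parameters
#'
#' The survey thresholds: a run of consecutive tRNA genes is a cluster when
#' it has at least `min_genes` genes and a density of at least `min_density`
#' tRNA genes per kb over its span (first member start to last member end).
#' Both comparisons are inclusive.
#'
#' @param min_genes Minimum number of member genes (default 15).
#' @param min_density Minimum density in tRNA genes per kb (default 2.0).
#' @param circular Treat the genome as circular (default FALSE).
#' @return A list of class `cluster_scan_params`.
#' @export
cluster_scan_params <- function(min_genes = 15L, min_density = 2.0,
                                circular = FALSE) {
  min_genes <- as.integer(min_genes)
  stopifnot(min_genes >= 2L, min_density > 0)
  structure(list(min_genes = min_genes, min_density = min_density,
                 circular = circular),
            class = "cluster_scan_params")
}

#' Detect tRNA gene clusters in one genome
#'
#' Finds all maximal windows of consecutive tRNA genes satisfying both the
#' gene-count and density thresholds. A window is maximal when no strictly
#' containing window also satisfies both. When two maximal qualifying
#' windows overlap (their union necessarily fails the density test, or it
#' would itself qualify and neither would be maximal), the window with more
#' genes is reported first (tie: leftmost) and the remaining genes on either
#' side are re-scanned, so reported clusters are always disjoint.
#'
#' In circular mode the gene list is virtually doubled with coordinates
#' shifted by `genome_length`; a cluster crossing the origin is reported
#' once, with `span_end > genome_length` and `wraparound = TRUE`.
#'
#' Density is `n_genes / ((span_end - span_start)/1000)` with the span
#' measured from the first member's start to the last member's end, an
#' intrinsic property of the member genes.
#'
#' @param genes Data.frame of tRNA genes for a single genome (columns as in
#'   [read_trna_annotations()]), sorted by start.
#' @param genome_length Genome length in bp.
#' @param params A [cluster_scan_params()] object.
#' @return A data.frame with one row per cluster: `genome_id`,
#'   `cluster_index`, `span_start`, `span_end`, `n_genes`, `density`,
#'   `signature` (member isotypes in genomic order), `wraparound`, and a
#'   list-column `members` holding each cluster's member gene rows.
#' @export
#' @examples
#' g <- data.frame(genome_id = "g", start = seq(0, by = 500, length.out = 15),
#'                 end = seq(0, by = 500, length.out = 15) + 72,
#'                 strand = "+", isotype = rep("M", 15), anticodon = "CAT")
#' detect_clusters(g, genome_length = 10000)
detect_clusters <- function(genes, genome_length,
                            params = cluster_scan_params()) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (nrow(genes) > 0L) {
    if (length(unique(genes$genome_id)) > 1L) {
      stop("detect_clusters operates on a single genome")
    }
    if (is.unsorted(genes$start)) stop("genes must be sorted by start")
    if (min(genes$start) < 0 || max(genes$end) > genome_length) {
      stop("gene coordinates outside [0, genome_length]")
    }
  }
  n <- nrow(genes)
  empty <- empty_cluster_table()
  if (n == 0L) return(empty)

  if (isTRUE(params$circular) && n >= 1L) {
    aug <- genes
    aug$start <- aug$start + genome_length
    aug$end <- aug$end + genome_length
    work <- rbind(genes, aug)
    orig <- c(seq_len(n), seq_len(n))
  } else {
    work <- genes
    orig <- seq_len(n)
  }

  wins <- scan_segment(work$start, work$end, seq_len(nrow(work)),
                       params$min_genes, params$min_density)
  if (length(wins) == 0L) return(empty)

  rows <- lapply(wins, function(w) {
    idx <- w[1]:w[2]
    oidx <- orig[idx]
    if (anyDuplicated(oidx)) return(NULL)          # circular self-overlap
    if (work$start[w[1]] >= genome_length) return(NULL)  # circular duplicate
    mem <- genes[oidx, , drop = FALSE]
    span_start <- work$start[w[1]]
    span_end <- work$end[w[2]]
    data.frame(
      genome_id = genes$genome_id[1],
      span_start = span_start,
      span_end = span_end,
      n_genes = length(idx),
      density = length(idx) / ((span_end - span_start) / 1000),
      signature = paste(genes$isotype[oidx], collapse = ""),
      wraparound = span_end > genome_length,
      members = I(list(mem)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # Circular scans can report the same member set from both copies.
  keys <- vapply(out$members, function(m) paste(m$start, collapse = ","),
                 character(1))
  out <- out[!duplicated(keys), , drop = FALSE]
  out <- out[order(out$span_start), , drop = FALSE]
  out$cluster_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("genome_id", "cluster_index", "span_start", "span_end", "n_genes",
          "density", "signature", "wraparound", "members")]
}

empty_cluster_table <- function() {
  data.frame(genome_id = character(), cluster_index = integer(),
             span_start = integer(), span_end = integer(),
             n_genes = integer(), density = numeric(),
             signature = character(), wraparound = logical(),
             members = I(list()), stringsAsFactors = FALSE)
}

# Recursive scan of a contiguous index segment: find maximal qualifying
# windows; if they are pairwise disjoint report all, otherwise report the
# best (most genes, tie leftmost) and re-scan the flanking remainders.
# Returns a list of c(first_index, last_index) in the coordinates of the
# full gene vector.
scan_segment <- function(starts, ends, idx, min_genes, min_density) {
  m <- length(idx)
  if (m < min_genes) return(list())
  s <- starts[idx]
  e <- ends[idx]
  cnt <- outer(seq_len(m), seq_len(m), function(i, j) j - i + 1)
  span <- outer(s, e, function(si, ej) ej - si)
  Q <- cnt >= min_genes & cnt / (span / 1000) >= min_density
  Q[lower.tri(Q)] <- FALSE
  if (!any(Q)) return(list())
  # N[i,j] = number of qualifying windows [i',j'] with i' <= i and j' >= j;
  # a qualifying window is maximal iff it is the only one in its cone.
  A <- apply(Q, 2, cumsum)
  if (m == 1L) A <- matrix(A, 1L, 1L)
  N <- t(apply(A, 1, function(r) rev(cumsum(rev(r)))))
  mx <- which(Q & N == 1L, arr.ind = TRUE)
  wins <- lapply(seq_len(nrow(mx)), function(k) c(mx[k, 1], mx[k, 2]))
  wins <- wins[order(vapply(wins, `[`, numeric(1), 1))]
  overlapping <- FALSE
  if (length(wins) > 1L) {
    for (k in seq_len(length(wins) - 1L)) {
      if (wins[[k + 1L]][1] <= wins[[k]][2]) { overlapping <- TRUE; break }
    }
  }
  if (!overlapping) {
    return(lapply(wins, function(w) c(idx[w[1]], idx[w[2]])))
  }
  sizes <- vapply(wins, function(w) w[2] - w[1] + 1, numeric(1))
  best <- wins[[order(-sizes, vapply(wins, `[`, numeric(1), 1))[1]]]
  left <- if (best[1] > 1L) idx[seq_len(best[1] - 1L)] else integer()
  right <- if (best[2] < m) idx[(best[2] + 1L):m] else integer()
  c(scan_segment(starts, ends, left, min_genes, min_density),
    list(c(idx[best[1]], idx[best[2]])),
    scan_segment(starts, ends, right, min_genes, min_density))
}

#' Fraction of a genome's tRNA genes that are clustered
#'
#' @param genes tRNA gene table for one genome.
#' @param clusters Cluster table from [detect_clusters()] on those genes.
#' @return Number of cluster member genes divided by the total number of
#'   genes; 0 when there are no genes.
#' @export
fraction_clustered <- function(genes, clusters) {
  if (nrow(genes) == 0L) return(0)
  n_clustered <- sum(clusters$n_genes)
  n_clustered / nrow(genes)
}

#' CDS within and flanking a tRNA gene cluster
#'
#' Returns all CDS overlapping the cluster span extended by `window` bp on
#' each side (clipped at the genome bounds in linear mode). Each CDS is
#' tagged `within` when it overlaps the span itself, `flanking` otherwise.
#'
#' @param cluster One row of a [detect_clusters()] table.
#' @param cds CDS table for the same genome.
#' @param window Flank width in bp (default 2000).
#' @param genome_length Optional genome length for clipping.
#' @return The overlapping CDS rows with an added `region` column.
#' @export
extract_flank_genes <- function(cluster, cds, window = 2000,
                                genome_length = NULL) {
  lo <- cluster$span_start - window
  hi <- cluster$span_end + window
  if (!is.null(genome_length)) {
    lo <- max(0, lo)
    hi <- min(genome_length, hi)
  } else {
    lo <- max(0, lo)
  }
  hit <- cds$start < hi & cds$end > lo
  out <- cds[hit, , drop = FALSE]
  if (nrow(out)) {
    within <- out$start < cluster$span_end & out$end > cluster$span_start
    out$region <- ifelse(within, "within", "flanking")
  } else {
    out$region <- character(0)
  }
  rownames(out) <- NULL
  out
}
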