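# Independent oracles, written naively and kept separate from the package
# implementation.

# Brute-force cluster detector: enumerate every window of consecutive genes,
# keep those meeting both thresholds with no qualifying strict superwindow,
# and if any two overlap, report the one with most genes (tie: leftmost)
# and re-scan the flanking remainders. Returns a list of c(first, last)
# gene indices.
oracle_detect <- function(starts, ends, min_genes, min_density) {
  rec <- function(lo, hi) {
    if (hi < lo || hi - lo + 1 < min_genes) return(list())
    q1 <- integer(0); q2 <- integer(0)
    for (i in lo:hi) {
      for (j in i:hi) {
        cnt <- j - i + 1
        if (cnt < min_genes) next
        dens <- cnt / ((ends[j] - starts[i]) / 1000)
        if (dens >= min_density) { q1 <- c(q1, i); q2 <- c(q2, j) }
      }
    }
    if (length(q1) == 0L) return(list())
    keep <- vapply(seq_along(q1), function(k) {
      !any(q1 <= q1[k] & q2 >= q2[k] & (q1 < q1[k] | q2 > q2[k]))
    }, logical(1))
    w1 <- q1[keep]; w2 <- q2[keep]
    ord <- order(w1); w1 <- w1[ord]; w2 <- w2[ord]
    disjoint <- length(w1) < 2 || all(w1[-1] > w2[-length(w2)])
    if (disjoint) {
      return(lapply(seq_along(w1), function(k) c(w1[k], w2[k])))
    }
    b <- order(-(w2 - w1 + 1), w1)[1]
    c(rec(lo, w1[b] - 1), list(c(w1[b], w2[b])), rec(w2[b] + 1, hi))
  }
  rec(1, length(starts))
}

# Naive dynamic-programming Levenshtein distance.
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x); d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# Random tRNA gene instance: mixture of tight and wide spacings so dense
# runs of varying extent arise.
random_gene_instance <- function(n) {
  gaps <- ifelse(runif(n) < 0.75,
                 sample(30:400, n, replace = TRUE),
                 sample(1500:9000, n, replace = TRUE))
  starts <- cumsum(gaps)
  data.frame(genome_id = "r", start = starts, end = starts + 72L,
             strand = "+",
             isotype = sample(c("A", "C", "D", "E"), n, replace = TRUE),
             anticodon = NA_character_, stringsAsFactors = FALSE)
}

# Evenly spaced run of 72-bp tRNA genes covering exactly `span` bp.
uniform_run <- function(n, span, offset = 0L, isotype = "M",
                        anticodon = "CAT") {
  starts <- as.integer(round(seq(offset, offset + span - 72, length.out = n)))
  data.frame(genome_id = "g", start = starts, end = starts + 72L,
             strand = "+", isotype = rep_len(isotype, n),
             anticodon = rep_len(anticodon, n), stringsAsFactors = FALSE)
}

# Member windows of a detect_clusters() result as first/last start pairs,
# comparable with oracle output applied to the same gene table.
cluster_windows <- function(clusters, genes) {
  lapply(seq_len(nrow(clusters)), function(i) {
    mem <- clusters$members[[i]]
    c(match(mem$start[1], genes$start),
      match(mem$start[nrow(mem)], genes$start))
  })
}
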