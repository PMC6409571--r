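#' Canonicalize an isotype signature for orientation
#'
#' A cluster read on the opposite strand has its gene order reversed, so a
#' signature and its reversal describe the same arrangement. The canonical
#' form is the lexicographically smaller of the two.
#'
#' @param signature Non-empty string over the 23-letter isotype alphabet.
#' @param orient Apply orientation canonicalization (default TRUE); when
#'   FALSE the validated signature is returned unchanged.
#' @return The canonical signature string. Vectorized.
#' @export
#' @examples
#' canonicalize_signature("PEMN")  # "NMEP"
canonicalize_signature <- function(signature, orient = TRUE) {
  vapply(signature, function(sig) {
    if (is.na(sig) || nchar(sig) == 0L) stop("empty signature")
    ch <- strsplit(sig, "")[[1]]
    bad <- !ch %in% ISOTYPE_ALPHABET
    if (any(bad)) {
      stop("signature symbol(s) outside isotype alphabet: ",
           paste(unique(ch[bad]), collapse = ", "))
    }
    if (!orient) return(sig)
    rev_sig <- paste(rev(ch), collapse = "")
    if (rev_sig < sig) rev_sig else sig
  }, character(1), USE.NAMES = FALSE)
}

#' Group tRNA gene clusters by isotype arrangement
#'
#' Clusters with identical canonical signatures share a group. Groups are
#' numbered G1, G2, ... in decreasing member count, ties broken by
#' lexicographic canonical signature; size-1 groups are flagged singletons.
#'
#' @param clusters A [detect_clusters()]-style table (possibly concatenated
#'   over genomes) with columns `genome_id`, `cluster_index`, `signature`.
#' @param orient Canonicalize orientation before grouping (default TRUE).
#' @return A data.frame with `group_id`, `canonical_signature`, `n_members`,
#'   `is_singleton` and a list-column `members` of data.frames
#'   (genome_id, cluster_index).
#' @export
group_clusters <- function(clusters, orient = TRUE) {
  if (nrow(clusters) == 0L) {
    return(data.frame(group_id = character(),
                      canonical_signature = character(),
                      n_members = integer(), is_singleton = logical(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  canon <- canonicalize_signature(clusters$signature, orient = orient)
  parts <- split(seq_len(nrow(clusters)), canon)
  sizes <- vapply(parts, length, integer(1))
  ord <- order(-sizes, names(parts))
  parts <- parts[ord]
  sizes <- sizes[ord]
  members <- lapply(parts, function(ix) {
    m <- clusters[ix, c("genome_id", "cluster_index"), drop = FALSE]
    m <- m[order(m$genome_id, m$cluster_index), , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  data.frame(
    group_id = sprintf("G%d", seq_along(parts)),
    canonical_signature = names(parts),
    n_members = unname(sizes),
    is_singleton = unname(sizes) == 1L,
    members = I(unname(members)),
    stringsAsFactors = FALSE
  )
}

#' Edit distance between isotype signatures
#'
#' Levenshtein distance between canonicalized signatures, minimized over the
#' two orientation pairings, so that strand-of-reading never inflates the
#' distance.
#'
#' @param a,b Non-empty isotype signature strings.
#' @return Integer edit distance.
#' @export
#' @examples
#' signature_distance("NMEPAC", "AC")  # 4
signature_distance <- function(a, b) {
  ca <- canonicalize_signature(a)
  cb <- canonicalize_signature(b)
  cb_rev <- paste(rev(strsplit(cb, "")[[1]]), collapse = "")
  min(adist(ca, cb), adist(ca, cb_rev))
}

#' Report singletons near established cluster groups
#'
#' For each singleton, lists every multi-member group whose canonical
#' signature is within `max_distance` edits, quantifying the near-membership
#' relations that exact grouping keeps separate (e.g. a cluster differing
#' from a group only by a terminal deletion of a few genes).
#'
#' @param groups Output of [group_clusters()].
#' @param max_distance Maximum edit distance to report.
#' @return A data.frame (`singleton_signature`, `group_id`,
#'   `group_signature`, `distance`) sorted by distance then group_id.
#' @export
report_near_matches <- function(groups, max_distance) {
  singles <- groups[groups$is_singleton, , drop = FALSE]
  multis <- groups[!groups$is_singleton, , drop = FALSE]
  if (nrow(singles) == 0L || nrow(multis) == 0L || max_distance < 1L) {
    return(data.frame(singleton_signature = character(),
                      group_id = character(),
                      group_signature = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (i in seq_len(nrow(singles))) {
    for (j in seq_len(nrow(multis))) {
      d <- signature_distance(singles$canonical_signature[i],
                              multis$canonical_signature[j])
      if (d <= max_distance) {
        rows[[length(rows) + 1L]] <- data.frame(
          singleton_signature = singles$canonical_signature[i],
          group_id = multis$group_id[j],
          group_signature = multis$canonical_signature[j],
          distance = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(singleton_signature = character(),
                      group_id = character(),
                      group_signature = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, out$group_id, out$singleton_signature), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
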