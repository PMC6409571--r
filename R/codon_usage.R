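#' Decode an anticodon to its codon
#'
#' Exact Watson-Crick decoding: the codon is the reverse complement of the
#' anticodon. Wobble-expanded decoding is deliberately not offered.
#'
#' @param anticodon Character vector of 3-mers over A/C/G/T.
#' @return Character vector of codons.
#' @export
#' @examples
#' anticodon_to_codon("CAT")  # "ATG"
anticodon_to_codon <- function(anticodon) {
  ok <- grepl("^[ACGT]{3}$", anticodon)
  if (!all(ok)) {
    stop("anticodon(s) not a 3-mer over A/C/G/T: ",
         paste(unique(anticodon[!ok]), collapse = ", "))
  }
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(anticodon)))
}

#' Build a codon count table
#'
#' @param counts Named non-negative integer vector over codons (names are
#'   3-mers over A/C/G/T); codons absent from `counts` get zero.
#' @param source_id Identifier of the counted entity.
#' @param scope `"genome"` or `"gene"`.
#' @return A list of class `codon_count_table` with a full 64-codon `counts`
#'   vector, `source_id`, `scope`, and `n_skipped` (codons containing
#'   ambiguous bases that were dropped during counting).
#' @export
codon_count_table <- function(counts, source_id = "table",
                              scope = c("genome", "gene"),
                              n_skipped = 0L) {
  scope <- match.arg(scope)
  all64 <- ALL_CODONS()
  bad <- setdiff(names(counts), all64)
  if (length(bad)) {
    stop("not a codon over A/C/G/T: ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative codon count")
  full <- setNames(integer(64), all64)
  full[names(counts)] <- as.integer(counts)
  structure(list(counts = full, source_id = source_id, scope = scope,
                 n_skipped = as.integer(n_skipped)),
            class = "codon_count_table")
}

#' Count codons over a set of CDS
#'
#' Frame-0 codon counts summed over all coding-strand sequences. Codons
#' containing non-ACGT characters are skipped and tallied in `n_skipped`.
#'
#' @param cds CDS table (needs a `sequence` column) or a character vector of
#'   coding sequences with length divisible by 3.
#' @param source_id Identifier for the resulting table.
#' @param scope `"genome"` or `"gene"`.
#' @return A `codon_count_table`.
#' @export
#' @examples
#' count_codons("ATGAAATGA")$counts[c("ATG", "AAA", "TGA")]
count_codons <- function(cds, source_id = "cds",
                         scope = c("genome", "gene")) {
  scope <- match.arg(scope)
  seqs <- if (is.data.frame(cds)) cds$sequence else cds
  seqs <- toupper(seqs)
  if (any(nchar(seqs) %% 3L != 0L)) {
    stop("CDS sequence length not divisible by 3")
  }
  codons <- unlist(lapply(seqs, function(s) {
    if (nchar(s) == 0L) return(character())
    substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
  }))
  clean <- grepl("^[ACGT]{3}$", codons)
  tab <- table(codons[clean])
  codon_count_table(setNames(as.integer(tab), names(tab)),
                    source_id = source_id, scope = scope,
                    n_skipped = sum(!clean))
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F, RSCU(c) = count(c) * |F| /
#' sum of counts over F: the observed count relative to the mean of its
#' family, so 1 means no bias and values above/below 1 mean the codon is
#' used more/less than expected under uniform synonymous usage. Families
#' with zero total count are undefined and reported as NA, never 0. Stop
#' codons are excluded; the two single-codon families (Met/ATG, Trp/TGG)
#' have RSCU 1 whenever observed.
#'
#' @param table A `codon_count_table` (or named count vector).
#' @return A data.frame of class `rscu_profile` with columns `codon`,
#'   `amino_acid`, `count`, `rscu`, one row per sense codon; `source_id`
#'   kept as an attribute.
#' @export
compute_rscu <- function(table) {
  if (!inherits(table, "codon_count_table")) {
    table <- codon_count_table(table)
  }
  fams <- codon_families()
  rows <- lapply(names(fams), function(aa) {
    cods <- fams[[aa]]
    cnt <- table$counts[cods]
    tot <- sum(cnt)
    rscu <- if (tot > 0) unname(cnt) * length(cods) / tot
            else rep(NA_real_, length(cods))
    data.frame(codon = cods, amino_acid = aa, count = unname(cnt),
               rscu = rscu, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$codon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_id") <- table$source_id
  class(out) <- c("rscu_profile", "data.frame")
  out
}

#' Codon and isotype copy numbers of a cluster
#'
#' The per-cluster codon inventory: how many member tRNA genes decode each
#' codon (exact Watson-Crick reverse complement of the anticodon) and how
#' many carry each isotype. Members with unknown anticodons contribute to
#' the isotype counts only.
#'
#' @param cluster One row of a [detect_clusters()] table (with its
#'   `members` list-column).
#' @return A list of class `cluster_codon_pattern`: `genome_id`,
#'   `cluster_index`, `codon_copy_number` (named integer vector over decoded
#'   codons), `isotype_copy_number`, `n_codons` (distinct decoded codons),
#'   `n_genes`.
#' @export
cluster_codon_pattern <- function(cluster) {
  mem <- cluster$members[[1]]
  anti <- mem$anticodon
  known <- !is.na(anti)
  codons <- if (any(known)) anticodon_to_codon(anti[known]) else character()
  ctab <- table(codons)
  itab <- table(mem$isotype)
  structure(list(
    genome_id = cluster$genome_id,
    cluster_index = cluster$cluster_index,
    codon_copy_number = setNames(as.integer(ctab), names(ctab)),
    isotype_copy_number = setNames(as.integer(itab), names(itab)),
    n_codons = length(ctab),
    n_genes = nrow(mem)
  ), class = "cluster_codon_pattern")
}

#' Match a cluster's codons against a preferred-codon set
#'
#' The preferred set is the sense codons with RSCU strictly greater than 1
#' in the reference profile (a highly expressed gene such as the major
#' capsid protein, or the whole genome). Matching uses codon sets, not copy
#' numbers: the fraction is |preferred intersect supplied| / |preferred|.
#' Anticodons decoding stop codons (e.g. pyrrolysine/selenocysteine tRNAs)
#' can never match, since the preferred set contains sense codons only.
#'
#' @param pattern A [cluster_codon_pattern()].
#' @param profile An [compute_rscu()] profile for the target.
#' @param target_id Label for the target (e.g. `"genome"` or `"mcp"`).
#' @return One-row data.frame: `genome_id`, `cluster_index`, `target_id`,
#'   `n_preferred`, `n_matched`, `matching_fraction` (NA with a warning when
#'   the profile has no codon above 1).
#' @export
match_preferred_codons <- function(pattern, profile, target_id = "target") {
  preferred <- profile$codon[!is.na(profile$rscu) & profile$rscu > 1]
  supplied <- names(pattern$codon_copy_number)
  if (length(preferred) == 0L) {
    warning("no preferred codons (RSCU > 1) in profile; fraction undefined",
            call. = FALSE)
    frac <- NA_real_
    matched <- NA_integer_
  } else {
    matched <- length(intersect(preferred, supplied))
    frac <- matched / length(preferred)
  }
  data.frame(genome_id = pattern$genome_id,
             cluster_index = pattern$cluster_index,
             target_id = target_id,
             n_preferred = length(preferred),
             n_matched = matched,
             matching_fraction = frac,
             stringsAsFactors = FALSE)
}

#' Locate the major capsid protein CDS
#'
#' Picks the CDS whose product annotation matches `pattern`
#' (case-insensitive); with several matches the longest is chosen and all
#' matches are reported via a message.
#'
#' @param cds CDS table with `product` annotations.
#' @param pattern Regular expression for the product (default
#'   `"major capsid"`).
#' @return The selected CDS row, or NULL when absent.
#' @export
find_mcp <- function(cds, pattern = "major capsid") {
  if (nrow(cds) == 0L) return(NULL)
  hit <- !is.na(cds$product) & grepl(pattern, cds$product, ignore.case = TRUE)
  if (!any(hit)) return(NULL)
  cand <- cds[hit, , drop = FALSE]
  if (nrow(cand) > 1L) {
    message(nrow(cand), " CDS match '", pattern, "': ",
            paste(cand$cds_id, collapse = ", "), "; choosing the longest")
  }
  cand <- cand[order(-nchar(cand$sequence), cand$cds_id), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Cluster-by-codon copy-number matrix
#'
#' The cohort-wide codon inventory: one row per cluster, one column per
#' codon, entries the number of member tRNA genes decoding that codon.
#'
#' @param clusters A [detect_clusters()]-style table (rows from one or many
#'   genomes).
#' @return An integer matrix (clusters x 64 codons) with row names
#'   `genome_id:cluster_index`.
#' @export
codon_pattern_matrix <- function(clusters) {
  all64 <- ALL_CODONS()
  m <- matrix(0L, nrow = nrow(clusters), ncol = length(all64),
              dimnames = list(paste(clusters$genome_id,
                                    clusters$cluster_index, sep = ":"),
                              all64))
  for (i in seq_len(nrow(clusters))) {
    p <- cluster_codon_pattern(clusters[i, , drop = FALSE])
    m[i, names(p$codon_copy_number)] <- p$codon_copy_number
  }
  m
}
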