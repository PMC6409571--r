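all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

test_that("anticodon decoding is the reverse complement and an involution", {
  expect_equal(anticodon_to_codon("CAT"), "ATG")
  expect_equal(anticodon_to_codon("GAA"), "TTC")
  for (ac in all_codons()) {
    expect_equal(anticodon_to_codon(anticodon_to_codon(ac)), ac)
  }
  expect_error(anticodon_to_codon("CAN"), "CAN")
})

test_that("codon counting is frame-0 over all CDS, skipping ambiguity", {
  expect_equal(unname(count_codons("ATGATG")$counts["ATG"]), 2L)
  t2 <- count_codons("ATGTAA")
  expect_equal(unname(t2$counts[c("ATG", "TAA")]), c(1L, 1L))
  t3 <- count_codons(c("ATGAAA", "AAATGA"))
  expect_equal(unname(t3$counts[c("ATG", "AAA", "TGA")]), c(1L, 2L, 1L))
  expect_equal(sum(t3$counts), 4L)
  tn <- count_codons("ATGNNNAAA")
  expect_equal(tn$n_skipped, 1L)
  expect_equal(sum(tn$counts), 2L)
  expect_error(count_codons("ATGA"), "divisible")
})

test_that("RSCU follows the family-relative formula", {
  # 2-codon family with counts 3 and 1 -> 1.5 and 0.5
  p <- compute_rscu(c(AAA = 3L, AAG = 1L))
  expect_equal(p$rscu[p$codon == "AAA"], 1.5)
  expect_equal(p$rscu[p$codon == "AAG"], 0.5)
  # single-codon family: RSCU 1 whenever observed
  p2 <- compute_rscu(c(ATG = 7L))
  expect_equal(p2$rscu[p2$codon == "ATG"], 1)
  # unobserved families are NA, never 0
  expect_true(all(is.na(p2$rscu[p2$codon != "ATG"])))
  # stop codons never appear in the profile
  expect_false(any(c("TAA", "TAG", "TGA") %in% p$codon))
  expect_equal(nrow(p), 61L)
})

test_that("uniform synonymous usage gives RSCU exactly 1 everywhere", {
  fams <- codon_families()
  counts <- setNames(integer(0), character(0))
  for (f in fams) counts[f] <- 9L
  p <- compute_rscu(counts)
  expect_true(all(p$rscu == 1))
})

test_that("RSCU family sums equal family size; profile is scale-invariant", {
  set.seed(12)
  fams <- codon_families()
  for (k in 1:60) {
    counts <- setNames(rpois(61, 4), unlist(fams, use.names = FALSE))
    p <- compute_rscu(counts)
    sums <- tapply(p$rscu, p$amino_acid, sum)
    sizes <- vapply(fams, length, integer(1))[names(sums)]
    observed <- tapply(p$count, p$amino_acid, sum) > 0
    expect_equal(as.vector(sums[observed]), unname(sizes[observed]))
    expect_true(all(is.na(sums[!observed])))
    # multiplying all counts by a positive integer changes nothing
    p5 <- compute_rscu(counts * 5L)
    expect_equal(p5$rscu, p$rscu)
  }
})

mk_cluster <- function(isotypes, anticodons) {
  n <- length(isotypes)
  members <- data.frame(genome_id = "g", start = seq(0, by = 500,
                                                     length.out = n),
                        end = seq(0, by = 500, length.out = n) + 72,
                        strand = "+", isotype = isotypes,
                        anticodon = anticodons, stringsAsFactors = FALSE)
  data.frame(genome_id = "g", cluster_index = 1L, span_start = 0L,
             span_end = max(members$end), n_genes = n,
             density = n / (max(members$end) / 1000),
             signature = paste(isotypes, collapse = ""), wraparound = FALSE,
             members = I(list(members)), stringsAsFactors = FALSE)
}

test_that("cluster codon patterns count decoded codons and isotypes", {
  # degenerate redundancy: 15 identical anticodons supply a single codon
  cl <- mk_cluster(rep("M", 15), rep("CAT", 15))
  p <- cluster_codon_pattern(cl)
  expect_equal(p$codon_copy_number, c(ATG = 15L))
  expect_equal(p$n_codons, 1L)
  expect_equal(p$isotype_copy_number, c(M = 15L))

  # 13 distinct anticodons supply 13 codons; unknown anticodons count
  # toward isotypes only
  anti <- c("CAT", "GAA", "TTC", "AAA", "CCC", "GGG", "TTT", "ACG",
            "CGT", "GTA", "TAC", "AGC", "GCA", NA)
  iso <- c(rep("A", 13), "X")
  p2 <- cluster_codon_pattern(mk_cluster(iso, anti))
  expect_equal(p2$n_codons, 13L)
  expect_equal(sum(p2$codon_copy_number), 13L)
  expect_equal(sum(p2$isotype_copy_number), 14L)
})

test_that("preferred-codon matching uses sets with the RSCU > 1 rule", {
  profile <- compute_rscu(c(AAA = 3L, AAG = 1L, GGA = 5L, GGC = 1L,
                            GGG = 1L, GGT = 1L, ATG = 2L))
  # preferred: AAA (1.5), GGA (2.5); ATG sits exactly at 1 and is excluded
  cl <- mk_cluster(c("K", "G", "M"), c("TTT", "TCC", "CAT"))
  m <- match_preferred_codons(cluster_codon_pattern(cl), profile, "genome")
  expect_equal(m$n_preferred, 2L)
  expect_equal(m$n_matched, 2L)
  expect_equal(m$matching_fraction, 1.0)

  # half supplied
  cl2 <- mk_cluster("K", "TTT")
  m2 <- match_preferred_codons(cluster_codon_pattern(cl2), profile)
  expect_equal(m2$matching_fraction, 0.5)

  # disjoint
  cl3 <- mk_cluster("F", "AAA")  # supplies TTT only
  m3 <- match_preferred_codons(cluster_codon_pattern(cl3), profile)
  expect_equal(m3$matching_fraction, 0)

  # no preferred codons at all -> undefined
  flat <- compute_rscu(c(ATG = 5L))
  expect_warning(m4 <- match_preferred_codons(cluster_codon_pattern(cl3),
                                              flat), "undefined")
  expect_true(is.na(m4$matching_fraction))
})

test_that("matching fraction grows monotonically as codons are supplied", {
  set.seed(9)
  fams <- codon_families()
  counts <- setNames(rpois(61, 6) + 1L, unlist(fams, use.names = FALSE))
  profile <- compute_rscu(counts)
  sense <- profile$codon
  anticodons <- vapply(sense, anticodon_to_codon, character(1))
  ord <- sample(length(sense))
  prev <- -1
  for (k in c(1, 5, 15, 30, 61)) {
    sel <- ord[seq_len(k)]
    cl <- mk_cluster(rep("A", k), unname(anticodons[sel]))
    frac <- match_preferred_codons(cluster_codon_pattern(cl),
                                   profile)$matching_fraction
    expect_gte(frac, prev)
    prev <- frac
  }
  expect_equal(prev, 1.0)
})

test_that("the MCP is found by product annotation, longest wins", {
  cds <- data.frame(
    genome_id = "g", cds_id = c("a", "b", "c"),
    start = 0L, end = 0L, strand = "+",
    product = c("portal protein", "Major Capsid Protein E",
                "major capsid protein"),
    sequence = c(strrep("ACG", 10), strrep("ACG", 300), strrep("ACG", 400)),
    stringsAsFactors = FALSE)
  expect_message(hit <- find_mcp(cds), "2 CDS match")
  expect_equal(hit$cds_id, "c")
  expect_null(find_mcp(cds[1, , drop = FALSE]))
  expect_null(find_mcp(cds[0, , drop = FALSE]))
})

test_that("the cluster-by-codon matrix aggregates copy numbers", {
  cl <- rbind(mk_cluster(rep("M", 3), rep("CAT", 3)),
              mk_cluster(c("K", "F"), c("TTT", "AAA")))
  cl$cluster_index <- c(1L, 2L)
  m <- codon_pattern_matrix(cl)
  expect_equal(dim(m), c(2L, 64L))
  expect_equal(m["g:1", "ATG"], 3L)
  expect_equal(m["g:2", "AAA"], 1L)
  expect_equal(m["g:2", "TTT"], 1L)
  expect_equal(sum(m), 5L)
})
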