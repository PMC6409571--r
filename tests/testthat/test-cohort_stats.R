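test_that("genome summaries count tRNAs, clusters and isotypes", {
  # one genome with a fully clustered 20-isotype cluster, one without tRNAs
  iso20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  spec <- synthetic_genome_spec(
    40000, clusters = list(cluster_plan(20, 2.5,
                                        signature = paste(iso20,
                                                          collapse = ""))),
    seed = 5)
  g <- generate_genome(spec, "withtrna")
  cl <- detect_clusters(g$trna, 40000)
  genomes <- rbind(g$genome,
                   data.frame(genome_id = "empty", length_bp = 8000L,
                              gc_fraction = 0.5, circular = FALSE))
  s <- summarize_genomes(genomes, g$trna, cl)
  expect_equal(s$n_trna, c(20L, 0L))
  expect_equal(s$n_clustered, c(20L, 0L))
  expect_equal(s$fraction_clustered, c(1.0, NA))
  expect_equal(s$n_isotypes, c(20L, 0L))
  expect_equal(s$lifestyle, c("unknown", "unknown"))
  # conservation: clustered totals equal cluster member counts
  expect_equal(sum(s$n_clustered), sum(cl$n_genes))

  bad <- cl; bad$genome_id <- "nosuch"
  expect_error(summarize_genomes(genomes, g$trna, bad), "unknown genome")
})

test_that("Spearman correlation handles monotone, tied and constant data", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1.0)
  expect_equal(spearman_correlation(1:10, -(1:10))$rho, -1.0)
  r <- spearman_correlation(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  # invariance under strictly monotone transforms
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- spearman_correlation(x, y)
  r1 <- spearman_correlation(exp(x), y^3 + y)
  expect_equal(r1$rho, r0$rho)
  expect_equal(r1$p_value, r0$p_value)
  expect_warning(rc <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("group comparison reports U, medians and IQR as specified", {
  # fully separated groups: no (a, b) pair favors a
  r <- compare_groups(c(1, 2, 3), c(10, 20, 30))
  expect_equal(r$statistic, 0)
  expect_equal(r$median_a, 2)
  expect_equal(r$median_b, 20)
  # identical samples: U = n^2/2 and p near 1
  r2 <- compare_groups(1:9, 1:9)
  expect_equal(r2$statistic, 81 / 2)
  expect_gt(r2$p_value, 0.9)
  # 3-point median convention check
  r3 <- compare_groups(c(5, 29, 12), c(1, 2, 3))
  expect_equal(r3$median_a, 12)
  expect_equal(r3$iqr_lo_a, quantile(c(5, 12, 29), 0.25, names = FALSE))
  # too small for a p-value
  expect_true(is.na(compare_groups(c(1, 2), c(3, 4))$p_value))
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("U statistics from the two orderings sum to n_a * n_b", {
  set.seed(8)
  for (k in 1:30) {
    a <- sample(1:40, sample(3:12, 1), replace = TRUE)
    b <- sample(1:40, sample(3:12, 1), replace = TRUE)
    ua <- compare_groups(a, b)$statistic
    ub <- compare_groups(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
    expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)
  }
})

test_that("lifestyle is called from integrase annotations", {
  mk <- function(products) data.frame(
    genome_id = "g", cds_id = seq_along(products), start = 0L, end = 3L,
    strand = "+", product = products, sequence = "ATG",
    stringsAsFactors = FALSE)
  r <- classify_lifestyle(mk(c("terminase", "tyrosine integrase")))
  expect_equal(r$lifestyle, "temperate")
  expect_equal(r$integrase_subtype, "tyrosine")
  r2 <- classify_lifestyle(mk("Serine Integrase"))
  expect_equal(r2$integrase_subtype, "serine")
  expect_equal(classify_lifestyle(mk(c("portal", "capsid")))$lifestyle,
               "virulent")
  expect_equal(classify_lifestyle(mk("integrase"))$integrase_subtype,
               NA_character_)
  expect_equal(classify_lifestyle(mk("portal")[0, ])$lifestyle, "unknown")
})

test_that("family summaries report counts, ranges and average GC", {
  s <- data.frame(
    genome_id = c("a", "b", "c", "d"),
    length_bp = c(10000L, 50000L, 90000L, 7000L),
    gc_fraction = c(0.4, 0.5, 0.6, 0.3),
    n_trna = c(0L, 1L, 43L, 5L),
    n_clustered = 0L, n_clusters = 0L, fraction_clustered = NA,
    n_isotypes = 0L, lifestyle = "unknown", stringsAsFactors = FALSE)
  meta <- data.frame(genome_id = c("a", "b", "c"),
                     family = c("Siphoviridae", "Siphoviridae",
                                "Siphoviridae"),
                     stringsAsFactors = FALSE)
  fam <- summarize_families(s, meta)
  sip <- fam[fam$family == "Siphoviridae", ]
  expect_equal(sip$genomes_with_trna, "2/3")
  expect_equal(sip$trna_range, "1-43")
  expect_equal(sip$avg_gc_percent, 50.00)
  expect_equal(fam$family, c("Siphoviridae", "unclassified"))
  expect_equal(fam$n_genomes, c(3L, 1L))
})

test_that("cohorts with length-dependent tRNA counts give positive rho", {
  noiseless <- generate_cohort(200, trna_length_slope = 2e-4,
                               noise_sd = 0, seed = 21)
  r0 <- spearman_correlation(noiseless$length_bp, noiseless$n_trna)
  expect_gt(r0$rho, 0.99)
  noisy <- generate_cohort(200, trna_length_slope = 2e-4,
                           noise_sd = 10, seed = 21)
  r1 <- spearman_correlation(noisy$length_bp, noisy$n_trna)
  expect_gt(r1$rho, 0)
  expect_gt(r0$rho, r1$rho)
})
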