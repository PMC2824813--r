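toy_map <- function() {
  data.frame(snp_id = c("s1", "s2", "s3", "s4", "s5", "s5"),
             gene_id = c("A", "A", "B", "C", "C", "D"),
             rule_used = "tx_plus_500bp", stringsAsFactors = FALSE)
}

test_that("significant SNPs in a gene list are counted as a distinct set", {
  map <- toy_map()
  sig <- c("s1", "s3", "s5")
  expect_equal(count_list_snps(c("A", "B", "C", "D"), map, sig), 3L)
  expect_equal(count_list_snps("Z", map, sig), 0L)
  # s5 maps to both C and D but counts once
  expect_equal(count_list_snps(c("C", "D"), map, sig), 1L)
  expect_error(count_list_snps(character(0), map, sig), "empty")
  # brute-force set-intersection oracle on a random map
  set.seed(8)
  map2 <- data.frame(snp_id = sample(sprintf("s%02d", 1:40), 120, TRUE),
                     gene_id = sample(LETTERS[1:12], 120, TRUE))
  map2 <- unique(map2)
  sig2 <- sample(sprintf("s%02d", 1:40), 15)
  gl <- sample(LETTERS[1:12], 5)
  brute <- length(intersect(unique(map2$snp_id[map2$gene_id %in% gl]), sig2))
  expect_equal(count_list_snps(gl, map2, sig2), brute)
})

test_that("resampling p is reproducible and saturates at 1", {
  map <- toy_map()
  sig <- c("s1", "s3")
  universe <- c("A", "B", "C", "D")
  # list = universe: every resample reaches the observed count
  er <- resampling_empirical_p(universe, universe, map, sig,
                               n_resamples = 50, seed = 2)
  expect_equal(er$empirical_p, 1)
  expect_equal(er$observed_snps, 2L)
  # observed = 0 is never exceeded
  er0 <- resampling_empirical_p("D", universe, map, character(0),
                                n_resamples = 50, seed = 2)
  expect_equal(er0$empirical_p, 1)
  # bit-identical under the same seed, different under another
  a <- resampling_empirical_p(c("A", "B"), universe, map, sig,
                              n_resamples = 200, seed = 9)
  b <- resampling_empirical_p(c("A", "B"), universe, map, sig,
                              n_resamples = 200, seed = 9)
  expect_identical(a$empirical_p, b$empirical_p)
  expect_identical(a$null_counts, b$null_counts)
  # plug-in variant uses b/R
  pl <- resampling_empirical_p(universe, universe, map, sig,
                               n_resamples = 50, seed = 2,
                               p_type = "plug_in")
  expect_equal(pl$empirical_p, 1)
})

test_that("multi-gene SNPs are not double-counted in resamples", {
  # s5 belongs to C and D; drawing both genes must count it once
  map <- toy_map()
  sig <- "s5"
  er <- resampling_empirical_p(c("C", "D"), c("C", "D"), map, sig,
                               n_resamples = 20, seed = 1)
  expect_equal(er$observed_snps, 1L)
  expect_equal(er$empirical_p, 1)  # every resample draws {C, D}
})

test_that("expected interaction counts follow the background rate", {
  expect_lt(abs(expected_interactions(23, 1916, 15280) - 2.88), 0.01)
  expect_lt(abs(expected_interactions(66, 1916, 15280) - 8.27), 0.01)
  expect_equal(expected_interactions(40, 0, 1000), 0)
  # linearity in the gene-set size
  set.seed(4)
  n <- sample(1:500, 10)
  e1 <- sapply(n, expected_interactions, background_interacting = 321,
               background_total = 9876)
  expect_equal(e1, n * expected_interactions(1, 321, 9876), tolerance = 1e-12)
})

test_that("interaction goodness-of-fit matches its closed form", {
  ic <- interaction_chisq(23, 10, 1916, 15280)
  e <- 23 * 1916 / 15280
  chi2 <- (10 - e)^2 / e + ((23 - 10) - (23 - e))^2 / (23 - e)
  expect_equal(ic$expected, e, tolerance = 1e-12)
  expect_equal(ic$chi2, chi2, tolerance = 1e-12)
  expect_equal(ic$p, pchisq(chi2, 1, lower.tail = FALSE), tolerance = 1e-12)

  exact <- interaction_chisq(100, 25, 250, 1000)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)
  expect_error(interaction_chisq(10, 5, 1000, 1000), "degenerate")
})

test_that("binomial over-representation equals the exact tail sum", {
  lc <- c(adhesion = 16L, transport = 3L, unused = 0L)
  rc <- c(adhesion = 200L, transport = 300L, unused = 0L)
  out <- binomial_overrepresentation(lc, 139L, rc, 10000L)
  expect_equal(attr(out, "skipped"), "unused")
  k <- out[out$category == "adhesion", ]
  expect_equal(k$p_value,
               sum(dbinom(16:139, 139, 0.02)), tolerance = 1e-12)
  expect_equal(k$p_bonferroni, min(1, k$p_value * 2))
  # matching fractions are unremarkable
  even <- binomial_overrepresentation(c(x = 20L), 1000L, c(x = 20L), 1000L)
  expect_gt(even$p_value, 0.4)
  expect_error(binomial_overrepresentation(c(q = 2L), 10L, c(x = 5L), 100L),
               "absent")
})
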