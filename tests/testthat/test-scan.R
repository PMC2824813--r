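make_sim <- function(n_snps = 500, seed = 1, ...) {
  simulate_panel(sim_config(n_snps = n_snps, seed = seed, ...))
}

test_that("MAF is the fold of the mean frequency across populations", {
  expect_equal(compute_maf(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(compute_maf(c(0.9, 0.8, 0.7)), 0.2)
  set.seed(2)
  f <- runif(52)
  m <- sum(f) / 52          # independent summation
  expect_equal(compute_maf(f), min(m, 1 - m), tolerance = 1e-15)
  expect_equal(compute_maf(c(0.2, NA, 0.4)), 0.3)
  expect_error(compute_maf(c(NA_real_, NA_real_)), "missing")
})

test_that("scan results equal the single-SNP statistic applied per SNP", {
  sim <- make_sim(n_snps = 200, seed = 7)
  X <- sim$fm$freqs
  X[4, c(2, 9)] <- NA      # exercise the incomplete-row path
  X[10, ] <- 0.25          # constant row
  fm <- freq_matrix(sim$fm$snp_meta, X)
  sc <- scan_snps(fm, sim$env, scan_config(min_window = 10))
  expect_true("snp00010" %in% sc$skipped$snp_id)
  expect_equal(sc$skipped$reason[sc$skipped$snp_id == "snp00010"],
               "constant_frequency")
  for (id in c("snp00001", "snp00004", "snp00123")) {
    k <- match(id, sim$fm$snp_meta$snp_id)
    ok <- !is.na(X[k, ])
    ref <- kendall_tau_b(X[k, ok], sim$env[ok])
    row <- sc$results[sc$results$snp_id == id, ]
    expect_equal(row$tau, ref$tau, tolerance = 1e-13)
    expect_equal(row$p_value, ref$p_value, tolerance = 1e-13)
    expect_equal(row$n_used, ref$n_used)
  }
})

test_that("a monotone frequency-environment SNP scores tau near 1", {
  sim <- make_sim(n_snps = 60, seed = 3)
  X <- sim$fm$freqs
  X[1, ] <- 0.2 + 0.5 * (sim$env - min(sim$env)) / diff(range(sim$env))
  sc <- scan_snps(freq_matrix(sim$fm$snp_meta, X), sim$env,
                  scan_config(min_window = 10))
  row <- sc$results[1, ]
  expect_gt(row$tau, 0.8)
  expect_lt(row$p_value, 1e-6)
})

test_that("SNPs with too few populations are skipped with a reason", {
  sim <- make_sim(n_snps = 30, seed = 9)
  X <- sim$fm$freqs
  X[5, 1:45] <- NA
  sc <- scan_snps(freq_matrix(sim$fm$snp_meta, X), sim$env,
                  scan_config(min_window = 10))
  expect_equal(sc$skipped$reason[sc$skipped$snp_id == "snp00005"],
               "too_few_populations")
  expect_false("snp00005" %in% sc$results$snp_id)
})

test_that("MAF-matched percentile ranks match a brute-force recomputation", {
  sim <- make_sim(n_snps = 500, seed = 13)
  cfg <- scan_config(min_window = 50)
  sc <- scan_snps(sim$fm, sim$env, cfg)
  r <- maf_matched_rank(sc$results, cfg)

  at <- abs(r$tau); maf <- r$maf
  for (i in sample(nrow(r), 50)) {
    win <- which(abs(maf - maf[i]) <= cfg$maf_window)
    if (length(win) >= cfg$min_window) {   # unwidened windows only
      expect_equal(r$window_n[i], length(win))
      expected <- (sum(at[win] < at[i]) + 0.5 * (sum(at[win] == at[i]) - 1)) /
        (length(win) - 1)
      expect_equal(r$rank[i], expected, tolerance = 1e-12)
    } else {
      expect_true(r$window_widened[i])
      expect_equal(r$window_n[i], cfg$min_window)
    }
  }
})

test_that("degenerate rank windows behave as defined", {
  base <- data.frame(snp_id = paste0("s", 1:101), chrom = "1", pos = 1:101,
                     tau = 0.5, p_value = 0.5, maf = 0.25, n_used = 52L,
                     window_n = NA_integer_, rank = NA_real_,
                     bonferroni_sig = NA, rank_sig = NA, final_sig = NA)
  cfg <- scan_config(min_window = 10)
  # one SNP strictly above all others
  r <- base; r$tau <- runif(101, 0, 0.4); r$tau[17] <- 0.9
  out <- maf_matched_rank(r, cfg)
  expect_equal(out$rank[17], 1)
  # all |tau| identical -> everyone sits at the midrank
  out2 <- maf_matched_rank(base, cfg)
  expect_true(all(out2$rank == 0.5))
  expect_error(maf_matched_rank(base[1:5, ], cfg), "min_window")
})

test_that("two-criterion calling requires both gates", {
  r <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                  tau = c(0.5, 0.6), p_value = c(0.04, 1e-9),
                  maf = c(0.2, 0.3), n_used = 52L, window_n = 100L,
                  rank = c(0.995, 0.98),
                  bonferroni_sig = NA, rank_sig = NA, final_sig = NA)
  out <- call_significant(r, scan_config(alpha = 0.05), n_tests = 1L)
  expect_true(out$final_sig[1])     # p = 0.04 <= 0.05/1 and rank > 0.99
  expect_false(out$final_sig[2])    # rank gate fails despite tiny p
  expect_true(out$bonferroni_sig[2])
})

test_that("allele flips negate tau but leave p, MAF, rank and calls alone", {
  sim <- make_sim(n_snps = 300, seed = 17, frac_selected = 0.02, beta = 0.2)
  cfg <- scan_config(min_window = 30)
  a <- run_scan(sim$fm, sim$env, cfg)$results
  flip <- sim$fm
  flip$freqs <- 1 - flip$freqs
  b <- run_scan(flip, sim$env, cfg)$results
  expect_equal(b$tau, -a$tau, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  expect_equal(b$maf, a$maf, tolerance = 1e-12)
  expect_equal(b$rank, a$rank, tolerance = 1e-12)
  expect_equal(b$final_sig, a$final_sig)
})

test_that("ranks are invariant to monotone transforms of the environment", {
  sim <- make_sim(n_snps = 200, seed = 23)
  cfg <- scan_config(min_window = 30)
  a <- run_scan(sim$fm, sim$env, cfg)$results
  b <- run_scan(sim$fm, exp(sim$env / 10), cfg)$results
  expect_equal(a$tau, b$tau, tolerance = 1e-12)
  expect_equal(a$rank, b$rank, tolerance = 1e-12)
})
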