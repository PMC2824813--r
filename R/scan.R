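#' Minor allele frequency of one SNP
#'
#' The MAF is computed as the fold of the unweighted mean coded-allele
#' frequency across populations: `min(m, 1 - m)` with `m` the mean of the
#' non-missing frequencies. Averaging across populations (rather than
#' pooling individuals) matches the per-population structure of the scan.
#'
#' @param freqs Numeric vector of per-population coded-allele frequencies.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(freqs) {
  if (all(is.na(freqs))) stop("all frequencies missing")
  m <- mean(freqs, na.rm = TRUE)
  min(m, 1 - m)
}

#' Scan configuration
#'
#' @param alpha Family-wise Bonferroni level (0.05 for genome-wide scans,
#'   0.01 for targeted gene-list scans).
#' @param rank_cutoff A SNP must exceed this percentile rank of |tau| among
#'   MAF-matched SNPs to be called (default 0.99).
#' @param maf_window Half-width of the MAF matching window (default 0.01,
#'   i.e. SNPs within 1 percentage point of MAF).
#' @param min_window Minimum number of SNPs a MAF window must contain; too
#'   small windows are widened to the nearest SNPs by MAF distance.
#' @param min_populations Minimum populations with non-missing frequency
#'   for a SNP to enter the scan; the normal approximation of the tau null
#'   is unreliable below about 10.
#' @param use_partial If `TRUE`, report the partial Kendall coefficient
#'   conditioning on `covariate` instead of the plain coefficient.
#' @param covariate Optional per-population numeric vector (conditioning
#'   variable for the partial coefficient).
#' @return A `scan_config` list.
#' @export
scan_config <- function(alpha = 0.05, rank_cutoff = 0.99, maf_window = 0.01,
                        min_window = 50L, min_populations = 10L,
                        use_partial = FALSE, covariate = NULL) {
  stopifnot(alpha > 0, alpha < 1, rank_cutoff > 0, rank_cutoff < 1,
            maf_window > 0, min_window >= 2L, min_populations >= 3L)
  if (use_partial && is.null(covariate))
    stop("use_partial = TRUE requires a covariate")
  structure(list(alpha = alpha, rank_cutoff = rank_cutoff,
                 maf_window = maf_window, min_window = as.integer(min_window),
                 min_populations = as.integer(min_populations),
                 use_partial = use_partial, covariate = covariate),
            class = "scan_config")
}

#' Per-SNP association scan against an environmental variable
#'
#' For every SNP with enough non-missing populations, computes Kendall's
#' tau-b between the coded-allele frequencies and the environmental vector,
#' together with the tie-corrected two-sided normal p-value and the SNP's
#' MAF. The tau sign is reported relative to the coded allele; orientation
#' is arbitrary in most frequency panels, so downstream ranking uses |tau|.
#'
#' @param fm A [freq_matrix()].
#' @param env Per-population environmental vector (see
#'   [broadcast_to_populations()]); length must equal the number of
#'   population columns.
#' @param cfg A [scan_config()].
#' @return List with `results` (data frame: snp_id, chrom, pos, tau,
#'   p_value, maf, n_used, window_n, rank, bonferroni_sig, rank_sig,
#'   final_sig -- rank and flag columns `NA` until filled by
#'   [maf_matched_rank()] and [call_significant()]) and `skipped` (data
#'   frame: snp_id, reason).
#' @export
scan_snps <- function(fm, env, cfg = scan_config()) {
  X <- fm$freqs
  if (length(env) != ncol(X))
    stop("environment length does not match the number of populations")
  env <- as.numeric(env)
  if (length(unique(env)) < 2L) stop("environmental variable is constant")

  nsnp <- nrow(X)
  n_used <- as.integer(rowSums(!is.na(X)))
  distinct2 <- apply_distinct2(X)
  usable <- n_used >= cfg$min_populations & distinct2
  reason <- rep(NA_character_, nsnp)
  reason[n_used < cfg$min_populations] <- "too_few_populations"
  reason[n_used >= cfg$min_populations & !distinct2] <- "constant_frequency"

  tau <- p <- zst <- rep(NA_real_, nsnp)
  complete <- n_used == ncol(X)
  fast <- usable & complete
  if (any(fast)) {
    kr <- kendall_rows(X[fast, , drop = FALSE], env)
    tau[fast] <- kr$tau; p[fast] <- kr$p_value; zst[fast] <- kr$statistic
    if (any(kr$undefined)) {
      k <- which(fast)[kr$undefined]
      usable[k] <- FALSE; reason[k] <- "constant_frequency"
    }
  }
  for (k in which(usable & !complete)) {
    ok <- !is.na(X[k, ])
    if (length(unique(env[ok])) < 2L) {
      usable[k] <- FALSE; reason[k] <- "constant_environment"; next
    }
    kt <- kendall_tau_b(X[k, ok], env[ok])
    tau[k] <- kt$tau; p[k] <- kt$p_value; zst[k] <- kt$statistic
  }

  if (cfg$use_partial) {
    cov <- as.numeric(cfg$covariate)
    if (length(cov) != ncol(X)) stop("covariate length mismatch")
    for (k in which(usable)) {
      ok <- !is.na(X[k, ])
      pk <- partial_kendall(X[k, ok], env[ok], cov[ok])
      tau[k] <- pk$tau; p[k] <- pk$p_value; zst[k] <- pk$statistic
    }
  }

  maf <- pmin(rowMeans(X, na.rm = TRUE), 1 - rowMeans(X, na.rm = TRUE))
  keep <- which(usable)
  if (!length(keep)) warning("no usable SNPs in scan")
  results <- data.frame(
    snp_id = fm$snp_meta$snp_id[keep],
    chrom = fm$snp_meta$chrom[keep],
    pos = fm$snp_meta$pos[keep],
    tau = tau[keep], p_value = p[keep], maf = maf[keep],
    n_used = n_used[keep],
    window_n = NA_integer_, rank = NA_real_,
    bonferroni_sig = NA, rank_sig = NA, final_sig = NA,
    stringsAsFactors = FALSE)
  skipped <- data.frame(snp_id = fm$snp_meta$snp_id[!usable],
                        reason = reason[!usable], stringsAsFactors = FALSE)
  list(results = results, skipped = skipped)
}

apply_distinct2 <- function(X) {
  rng <- cbind(suppressWarnings(apply(X, 1L, min, na.rm = TRUE)),
               suppressWarnings(apply(X, 1L, max, na.rm = TRUE)))
  is.finite(rng[, 1L]) & is.finite(rng[, 2L]) & rng[, 1L] < rng[, 2L]
}

#' Percentile rank of |tau| among MAF-matched SNPs
#'
#' Demographic history inflates raw correlation statistics, and the
#' inflation depends on allele frequency. Each SNP is therefore ranked
#' within the empirical distribution of |tau| over all SNPs of similar MAF
#' (within `maf_window`); a high percentile rank marks the SNP as extreme
#' relative to frequency-matched peers rather than relative to a parametric
#' null. Windows holding fewer than `min_window` SNPs are widened
#' symmetrically by nearest MAF distance. The rank uses midranks for tied
#' |tau| and excludes the SNP itself:
#' `rank = (#less + 0.5 #equal) / (window_n - 1)`.
#'
#' @param results Results data frame from [scan_snps()].
#' @param cfg A [scan_config()].
#' @return The data frame with `window_n` and `rank` filled, plus a logical
#'   `window_widened` column.
#' @export
maf_matched_rank <- function(results, cfg = scan_config()) {
  N <- nrow(results)
  if (N < cfg$min_window)
    stop("fewer SNPs (", N, ") than min_window (", cfg$min_window, ")")
  ord <- order(results$maf)
  m <- results$maf[ord]
  at <- abs(results$tau[ord])
  w <- cfg$maf_window

  lo <- findInterval(m - w, m, left.open = TRUE) + 1L  # first j: m[j] >= m - w
  hi <- findInterval(m + w, m)                         # last  j: m[j] <= m + w
  widened <- logical(N)
  rk <- numeric(N); wn <- integer(N)
  for (i in seq_len(N)) {
    l <- lo[i]; h <- hi[i]
    while (h - l + 1L < cfg$min_window) {
      widened[i] <- TRUE
      dl <- if (l > 1L) m[i] - m[l - 1L] else Inf
      dh <- if (h < N) m[h + 1L] - m[i] else Inf
      if (dl <= dh) l <- l - 1L else h <- h + 1L
    }
    ti <- at[i]
    win <- at[l:h]
    wn[i] <- h - l + 1L
    rk[i] <- (sum(win < ti) + 0.5 * (sum(win == ti) - 1)) / (wn[i] - 1L)
  }
  results$window_n[ord] <- wn
  results$rank[ord] <- rk
  results$window_widened <- FALSE
  results$window_widened[ord] <- widened
  results
}

#' Call significant SNPs under the two-criterion rule
#'
#' A SNP is called only if it survives Bonferroni correction at level
#' `alpha` over the SNPs tested in the analysis set *and* its |tau|
#' percentile rank among MAF-matched SNPs exceeds `rank_cutoff`. The joint
#' requirement couples a parametric threshold with the empirical,
#' demography-absorbing null.
#'
#' @param results Results with ranks filled by [maf_matched_rank()].
#' @param cfg A [scan_config()].
#' @param n_tests Bonferroni denominator; defaults to the number of SNPs in
#'   `results` (the analysis set actually tested).
#' @return The data frame with `bonferroni_sig`, `rank_sig` and `final_sig`
#'   set.
#' @export
call_significant <- function(results, cfg = scan_config(),
                             n_tests = nrow(results)) {
  stopifnot(n_tests >= 1L)
  if (anyNA(results$rank)) stop("ranks missing: run maf_matched_rank() first")
  results$bonferroni_sig <- results$p_value <= cfg$alpha / n_tests
  results$rank_sig <- results$rank > cfg$rank_cutoff
  results$final_sig <- results$bonferroni_sig & results$rank_sig
  results
}

#' Full scan: correlations, MAF-matched ranks, significance calls
#'
#' Convenience wrapper running [scan_snps()], [maf_matched_rank()] and
#' [call_significant()] in sequence.
#'
#' @inheritParams scan_snps
#' @param n_tests Bonferroni denominator (defaults to SNPs tested).
#' @return List with `results` (fully annotated) and `skipped`.
#' @export
run_scan <- function(fm, env, cfg = scan_config(), n_tests = NULL) {
  sc <- scan_snps(fm, env, cfg)
  if (nrow(sc$results) >= cfg$min_window) {
    sc$results <- maf_matched_rank(sc$results, cfg)
    if (is.null(n_tests)) n_tests <- nrow(sc$results)
    sc$results <- call_significant(sc$results, cfg, n_tests)
  }
  sc
}
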