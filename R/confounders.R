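#' Climate confounder screen for significant SNPs
#'
#' Pathogen diversity co-varies with climate, so an allele-frequency signal
#' attributed to pathogen pressure must be checked against temperature and
#' radiation. Each significant SNP is correlated (Kendall tau-b, two-sided
#' tie-corrected p) with every climate variable broadcast to populations;
#' Bonferroni correction uses the total number of SNP x variable tests in
#' the report. Nothing is filtered automatically: the report flags
#' correlations, and `strict = TRUE` additionally returns the SNPs that
#' fail the screen so callers can drop them.
#'
#' @param fm A [freq_matrix()].
#' @param sig_snp_ids SNP ids to screen.
#' @param climate Climate table from [read_climate_table()].
#' @param panel Panel data frame (population, country).
#' @param alpha Family-wise level for the screen (default 0.05).
#' @param strict If `TRUE`, include `dropped_snps` in the output.
#' @return List with `report` (snp_id, variable, tau, p_value,
#'   p_bonferroni, bonferroni_sig), `any_significant`, `n_tests`,
#'   `skipped_variables`, and optionally `dropped_snps`.
#' @export
confounder_screen <- function(fm, sig_snp_ids, climate, panel,
                              alpha = 0.05, strict = FALSE) {
  vars <- c("tmin", "tmax", "sw_flux")
  idx <- match(sig_snp_ids, fm$snp_meta$snp_id)
  if (anyNA(idx))
    stop("SNP id(s) not in frequency matrix: ",
         paste(sig_snp_ids[is.na(idx)], collapse = ", "))
  skipped <- character(0L)
  rows <- list()
  for (v in vars) {
    cv <- stats::setNames(climate[[v]], climate$country)
    env <- broadcast_to_populations(panel, cv, name = v)
    if (length(unique(env)) < 2L) { skipped <- c(skipped, v); next }
    for (k in idx) {
      x <- fm$freqs[k, ]
      kt <- kendall_tau_b(x, env)
      rows[[length(rows) + 1L]] <-
        data.frame(snp_id = fm$snp_meta$snp_id[k], variable = v,
                   tau = kt$tau, p_value = kt$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), variable = character(),
               tau = numeric(), p_value = numeric())
  n_tests <- nrow(report)
  report$p_bonferroni <- pmin(1, report$p_value * n_tests)
  report$bonferroni_sig <- if (n_tests)
    report$p_value <= alpha / n_tests else logical(0L)
  out <- list(report = report,
              any_significant = any(report$bonferroni_sig),
              n_tests = n_tests, skipped_variables = skipped)
  if (strict)
    out$dropped_snps <- unique(report$snp_id[report$bonferroni_sig])
  out
}
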