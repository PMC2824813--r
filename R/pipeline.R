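#' Run the full scan pipeline from a configuration
#'
#' Orchestrates the stages diversity -> scan -> rank -> call -> annotate ->
#' enrich -> confounders from a single structured configuration, writing
#' every stage output as a plain TSV plus a JSON-like manifest (input
#' checksums, parameter echo, per-stage timings and tallies). Stages whose
#' inputs are absent from the configuration are skipped.
#'
#' Configuration fields (YAML file or R list):
#' \describe{
#'   \item{inputs}{`panel` (required), `frequency` (required), `presence`,
#'     `genes`, `climate`, `gene_lists` (named list of files, one symbol
#'     per line).}
#'   \item{scan}{`alpha`, `rank_cutoff`, `maf_window`, `min_window`.}
#'   \item{enrichment}{`n_resamples` (default 10000).}
#'   \item{upstream_bp}{Gene-assignment window (default 500).}
#'   \item{genic_k}{Controls per significant SNP in the genic test
#'     (default 10).}
#'   \item{seed}{Mandatory integer seed for all stochastic stages.}
#'   \item{outdir}{Output directory.}
#' }
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param outdir Overrides `config$outdir` if given.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs))
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  ins <- config$inputs
  for (f in unlist(ins[c("panel", "frequency", "presence", "genes", "climate")]))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  for (f in unlist(ins$gene_lists))
    if (!file.exists(f)) stop("gene list file not found: ", f)
  if (is.null(ins$panel) || is.null(ins$frequency))
    stop("config$inputs must name at least 'panel' and 'frequency'")

  sc <- config$scan %||% list()
  cfg <- scan_config(alpha = sc$alpha %||% 0.05,
                     rank_cutoff = sc$rank_cutoff %||% 0.99,
                     maf_window = sc$maf_window %||% 0.01,
                     min_window = sc$min_window %||% 50L)
  upstream_bp <- config$upstream_bp %||% 500L
  n_resamples <- (config$enrichment %||% list())$n_resamples %||% 10000L
  genic_k <- config$genic_k %||% 10L

  fm <- NULL
  paths <- list()
  timings <- list()
  tally <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    on.exit(timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3))
    force(expr)
  }

  panel <- stage("read", {
    p <- read_population_table(ins$panel)
    fm <- read_frequency_matrix(ins$frequency, panel = p)
    p
  })

  env <- stage("diversity", {
    if (!is.null(ins$presence)) {
      div <- compute_diversity(read_presence_matrix(ins$presence))
    } else if ("virus_diversity" %in% names(panel)) {
      div <- tapply(panel$virus_diversity, panel$country, unique)
    } else stop("no presence matrix and no virus_diversity column in panel")
    e <- broadcast_to_populations(panel, div, name = "virus_diversity")
    paths$env <- write_tsv(data.frame(population = names(e), value = as.numeric(e)),
                            file.path(outdir, "env.tsv"))
    e
  })

  scan <- stage("scan", {
    s <- run_scan(fm, env, cfg)
    tally$snps_tested <- nrow(s$results)
    tally$snps_skipped <- nrow(s$skipped)
    tally$snps_significant <- sum(s$results$final_sig %in% TRUE)
    paths$scan_results <- write_tsv(s$results,
                                     file.path(outdir, "scan_results.tsv"))
    paths$skip_report <- write_tsv(s$skipped,
                                    file.path(outdir, "skip_report.tsv"))
    s
  })
  results <- scan$results
  sig_ids <- results$snp_id[results$final_sig %in% TRUE]

  map <- NULL
  if (!is.null(ins$genes)) stage("annotate", {
    genes <- read_gene_models(ins$genes)
    map <- assign_snps_to_genes(fm$snp_meta, genes, upstream_bp)
    tally$genes <- nrow(genes)
    tally$snp_gene_pairs <- nrow(map)
    paths$snp_gene_map <- write_tsv(map, file.path(outdir, "snp_gene_map.tsv"))
    if (length(sig_ids)) {
      gt <- tryCatch(genic_enrichment_test(results, map, cfg, k = genic_k,
                                           seed = seed),
                     error = function(e) {
                       warning("genic test skipped: ", conditionMessage(e))
                       NULL
                     })
      if (!is.null(gt))
      paths$genic_test <- write_tsv(
        data.frame(sig_genic = gt$table[1, 1], sig_non_genic = gt$table[1, 2],
                   control_genic = gt$table[2, 1],
                   control_non_genic = gt$table[2, 2],
                   chi2 = gt$chi2, p = gt$p, k = gt$k, seed = gt$seed),
        file.path(outdir, "genic_test.tsv"))
    }
  })

  if (!is.null(ins$gene_lists) && !is.null(map)) stage("enrich", {
    rows <- lapply(names(ins$gene_lists), function(nm) {
      gl <- readLines(ins$gene_lists[[nm]])
      gl <- gl[nzchar(gl)]
      er <- resampling_empirical_p(gl, map = map, sig_snp_ids = sig_ids,
                                   n_resamples = n_resamples, seed = seed,
                                   list_name = nm)
      data.frame(list_name = nm, m_genes = er$m_genes,
                 observed = er$observed_snps, n_resamples = er$n_resamples,
                 empirical_p = er$empirical_p, seed = er$seed)
    })
    paths$enrichment <- write_tsv(do.call(rbind, rows),
                                   file.path(outdir, "enrichment.tsv"))
  })

  if (!is.null(ins$climate)) stage("confound", {
    climate <- read_climate_table(ins$climate)
    cs <- confounder_screen(fm, sig_ids, climate, panel, alpha = cfg$alpha)
    tally$confounded <- sum(cs$report$bonferroni_sig)
    paths$confounders <- write_tsv(cs$report,
                                    file.path(outdir, "confounders.tsv"))
  })

  manifest <- list(
    inputs = lapply(Filter(Negate(is.null),
                           c(ins[c("panel", "frequency", "presence",
                                   "genes", "climate")],
                             ins$gene_lists)),
                    function(f) unname(tools::md5sum(f))),
    parameters = list(alpha = cfg$alpha, rank_cutoff = cfg$rank_cutoff,
                      maf_window = cfg$maf_window,
                      min_window = cfg$min_window,
                      upstream_bp = upstream_bp,
                      n_resamples = n_resamples, seed = seed),
    tallies = tally, timings_sec = timings)
  paths$manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
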