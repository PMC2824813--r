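#' Simulation configuration for a structured allele-frequency panel
#'
#' Defaults emulate the worldwide human panel the scan was designed for:
#' 52 populations nested in 21 countries on 7 continents, so that a
#' country-level environmental variable produces the same heavy tie
#' structure, and hierarchical Balding-Nichols drift producing the shared
#' demographic signal that the MAF-matched empirical null exists to
#' absorb. Drift intensities default to an HGDP-like partition of global
#' differentiation: `fst_continent = 0.08` between continents and
#' `fst_population = 0.02` between populations within a continent
#' (global FST about 0.1, mostly continental). The environmental value is
#' drawn per country as an integer uniform on `env_range` (default 39-55,
#' the span of observed per-country virus diversity).
#'
#' @param n_snps Number of SNPs to simulate.
#' @param n_populations,n_countries,n_continents Panel structure;
#'   populations are spread over countries, countries over continents, as
#'   evenly as possible.
#' @param fst_continent,fst_population Balding-Nichols F parameters in
#'   (0,1) for the continent and population levels.
#' @param frac_selected Fraction of SNPs whose frequencies track the
#'   environment.
#' @param beta Effect size: frequency shift per standard deviation of the
#'   country-level environment.
#' @param maf_floor Ancestral frequencies are uniform on
#'   `(maf_floor, 1 - maf_floor)`.
#' @param env_range Integer range for the per-country environment.
#' @param seed Integer seed; all outputs are a pure function of the
#'   configuration including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps, n_populations = 52L, n_countries = 21L,
                       n_continents = 7L, fst_continent = 0.08,
                       fst_population = 0.02, frac_selected = 0,
                       beta = 0.2, maf_floor = 0.05,
                       env_range = c(39L, 55L), seed = 1L) {
  stopifnot(n_snps >= 1L, n_countries <= n_populations,
            n_continents <= n_countries,
            fst_continent > 0, fst_continent < 1,
            fst_population > 0, fst_population < 1,
            frac_selected >= 0, frac_selected < 1,
            maf_floor > 0, maf_floor < 0.5)
  structure(list(n_snps = as.integer(n_snps),
                 n_populations = as.integer(n_populations),
                 n_countries = as.integer(n_countries),
                 n_continents = as.integer(n_continents),
                 fst_continent = fst_continent,
                 fst_population = fst_population,
                 frac_selected = frac_selected, beta = beta,
                 maf_floor = maf_floor,
                 env_range = as.integer(env_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured panel with optional environment-associated SNPs
#'
#' Ancestral frequencies are drawn uniform on `(maf_floor, 1 - maf_floor)`;
#' continental frequencies follow a Beta distribution around the ancestral
#' value with drift `fst_continent`, and population frequencies a Beta
#' around their continental value with `fst_population` (the
#' Balding-Nichols model applied twice). A per-country environment is drawn
#' independently and broadcast to populations. For a `frac_selected`
#' fraction of SNPs the population frequency is shifted by
#' `beta * standardized country environment` and clamped to \[0.01, 0.99\],
#' creating a monotone frequency-environment association on top of the
#' drift. With `beta = 0` no SNPs are marked selected.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel` (population, country, continent, n_sampled),
#'   `fm` (a [freq_matrix()]), `env` (per-population vector) and `truth`
#'   (list: selected_snp_ids, beta per selected SNP, env_country, config).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  np <- cfg$n_populations; nc <- cfg$n_countries; nk <- cfg$n_continents

  country_of_pop <- sort(rep_len(seq_len(nc), np))
  continent_of_country <- sort(rep_len(seq_len(nk), nc))
  panel <- data.frame(
    population = sprintf("pop%02d", seq_len(np)),
    country = sprintf("C%02d", country_of_pop),
    continent = sprintf("K%d", continent_of_country[country_of_pop]),
    n_sampled = sample(5:45, np, replace = TRUE),
    stringsAsFactors = FALSE)

  env_country <- stats::setNames(
    sample(seq(cfg$env_range[1L], cfg$env_range[2L]), nc, replace = TRUE),
    sprintf("C%02d", seq_len(nc)))
  env <- broadcast_to_populations(panel, env_country, name = "synthetic_env")

  ns <- cfg$n_snps
  p0 <- stats::runif(ns, cfg$maf_floor, 1 - cfg$maf_floor)
  bn <- function(p, f) {
    # Balding-Nichols draw around p with drift f; guard the open interval
    q <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
    pmin(pmax(q, 1e-9), 1 - 1e-9)
  }
  pcont <- matrix(bn(rep(p0, nk), cfg$fst_continent), ns, nk)
  freqs <- matrix(NA_real_, ns, np,
                  dimnames = list(sprintf("snp%05d", seq_len(ns)),
                                  panel$population))
  cont_idx <- continent_of_country[country_of_pop]
  for (k in seq_len(nk)) {
    cols <- which(cont_idx == k)
    freqs[, cols] <- bn(rep(pcont[, k], length(cols)), cfg$fst_population)
  }

  selected <- integer(0L)
  if (cfg$frac_selected > 0 && cfg$beta != 0) {
    n_sel <- round(cfg$frac_selected * ns)
    selected <- sort(sample.int(ns, n_sel))
    zc <- (env_country - mean(env_country)) / stats::sd(env_country)
    z_pop <- zc[panel$country]
    shift <- outer(rep(cfg$beta, n_sel), z_pop)
    freqs[selected, ] <- pmin(pmax(freqs[selected, , drop = FALSE] + shift,
                                   0.01), 0.99)
  }

  meta <- data.frame(snp_id = rownames(freqs), chrom = "1",
                     pos = seq_len(ns) * 1000L, coded_allele = "A",
                     stringsAsFactors = FALSE)
  truth <- list(selected_snp_ids = rownames(freqs)[selected],
                beta = stats::setNames(rep(cfg$beta, length(selected)),
                                       rownames(freqs)[selected]),
                ancestral = stats::setNames(p0, rownames(freqs)),
                env_country = env_country, config = cfg)
  list(panel = panel, fm = freq_matrix(meta, freqs), env = env, truth = truth)
}

#' Simulate gene models and gene lists over a synthetic panel
#'
#' Places non-overlapping genes over contiguous runs of SNPs so that a
#' `genic_fraction` of SNPs falls inside transcribed spans, then builds one
#' "enriched" gene list preferentially containing the genes that hold
#' selected SNPs and one size-matched random control list, plus a random
#' interacting-gene flag table.
#'
#' @param sim Output of [simulate_panel()].
#' @param n_genes Number of genes to place.
#' @param genic_fraction Fraction of SNPs covered by genes, in \[0,1\].
#' @param list_size Genes per list (default `min(50, n_genes)`).
#' @param interacting_fraction Fraction of genes flagged as interacting.
#' @param seed Integer seed.
#' @return List with `genes` (gene-model data frame), `lists`
#'   (`enriched`, `control`), and `interactions` (gene_id, interacts).
#' @export
simulate_annotation <- function(sim, n_genes = 200L, genic_fraction = 0.5,
                                list_size = NULL, interacting_fraction = 0.2,
                                seed = 1L) {
  stopifnot(n_genes >= 1L, genic_fraction >= 0, genic_fraction <= 1)
  set.seed(seed)
  meta <- sim$fm$snp_meta
  ns <- nrow(meta)
  if (is.null(list_size)) list_size <- min(50L, n_genes)

  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = "1", start = NA_integer_, end = NA_integer_,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  n_genic <- round(genic_fraction * ns)
  if (n_genic > 0L) {
    # split the genic SNPs into n_genes contiguous runs along the chromosome
    per_gene <- diff(round(seq(0, n_genic, length.out = n_genes + 1L)))
    starts_snp <- cumsum(c(1L, per_gene[-n_genes] +
                             diff(round(seq(0, ns - n_genic,
                                            length.out = n_genes + 1L)))[-n_genes]))
    pos <- meta$pos
    first <- starts_snp
    last <- starts_snp + pmax(per_gene - 1L, 0L)
    has <- per_gene > 0L
    genes$start[has] <- pos[first[has]] - 100L      # 0-based start, inside gap
    genes$end[has] <- pos[last[has]] + 100L
    genes <- genes[has, , drop = FALSE]
  } else {
    genes <- genes[0L, , drop = FALSE]
  }
  rownames(genes) <- NULL

  map <- assign_snps_to_genes(meta, genes, upstream_bp = 0L)
  sel <- sim$truth$selected_snp_ids
  sel_genes <- unique(map$gene_id[map$snp_id %in% sel])
  pool <- setdiff(genes$gene_id, sel_genes)
  need <- max(0L, list_size - length(sel_genes))
  enriched <- c(sel_genes, pool[sample.int(length(pool), min(need, length(pool)))])
  enriched <- enriched[seq_len(min(list_size, length(enriched)))]
  control <- sample(genes$gene_id, min(list_size, nrow(genes)))
  interactions <- data.frame(
    gene_id = genes$gene_id,
    interacts = stats::runif(nrow(genes)) < interacting_fraction,
    stringsAsFactors = FALSE)
  list(genes = genes, lists = list(enriched = enriched, control = control),
       interactions = interactions)
}

#' Recovery metrics against simulation truth
#'
#' @param truth Truth component of [simulate_panel()].
#' @param results Fully annotated scan results (after
#'   [call_significant()]) from the same panel.
#' @return List with `power` (fraction of selected SNPs called final_sig;
#'   `NA` if none were spiked), `fpr` (fraction of neutral SNPs called),
#'   `median_rank_selected`, `median_rank_neutral`, and counts.
#' @export
evaluate_recovery <- function(truth, results) {
  sel <- truth$selected_snp_ids
  if (length(sel) && !any(sel %in% results$snp_id) && nrow(results))
    stop("truth and results refer to disjoint SNP sets")
  is_sel <- results$snp_id %in% sel
  power <- if (length(sel)) mean(results$final_sig[is_sel]) else NA_real_
  fpr <- if (any(!is_sel)) mean(results$final_sig[!is_sel]) else NA_real_
  list(power = power, fpr = fpr,
       median_rank_selected = if (any(is_sel))
         stats::median(results$rank[is_sel]) else NA_real_,
       median_rank_neutral = if (any(!is_sel))
         stats::median(results$rank[!is_sel]) else NA_real_,
       n_selected = sum(is_sel), n_neutral = sum(!is_sel),
       n_called = sum(results$final_sig))
}
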