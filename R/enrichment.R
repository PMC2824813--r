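#' Count significant SNPs mapped to a gene list
#'
#' @param gene_list Character vector of gene symbols.
#' @param map SNP-gene map from [assign_snps_to_genes()].
#' @param sig_snp_ids Character vector of significant SNP ids.
#' @return Number of distinct significant SNPs mapping to at least one
#'   listed gene.
#' @export
count_list_snps <- function(gene_list, map, sig_snp_ids) {
  if (!length(gene_list)) stop("empty gene list")
  snps <- unique(map$snp_id[map$gene_id %in% gene_list])
  sum(snps %in% sig_snp_ids)
}

#' Empirical enrichment p-value by gene resampling
#'
#' Whether a gene list carries more significant SNPs than chance expects is
#' judged against random lists of the same size: `n_resamples` samples of
#' `m` genes are drawn uniformly without replacement from the universe of
#' genes covered by at least one SNP, and the significant-SNP count of each
#' sample forms the null distribution. The default estimator is
#' `(1 + b) / (1 + n_resamples)` with `b` the number of resamples reaching
#' the observed count, which cannot return zero; the plug-in form
#' `b / n_resamples` is also available. Uniform gene sampling ignores gene
#' length and SNP density, which is anti-conservative for SNP-dense lists;
#' `match_snp_count = TRUE` stratifies the resampling by per-gene SNP count
#' (bins 1, 2, 3, 4, >=5) as a more conservative alternative.
#'
#' @param gene_list Character vector of gene symbols.
#' @param universe Character vector: all genes covered by >= 1 SNP.
#'   Defaults to the genes present in `map`.
#' @param map SNP-gene map.
#' @param sig_snp_ids Significant SNP ids.
#' @param n_resamples Number of random gene samples (default 10000).
#' @param seed Integer seed.
#' @param p_type `"add_one"` (default) or `"plug_in"`.
#' @param match_snp_count Stratify resampling by per-gene SNP count.
#' @param list_name Label carried into the result.
#' @return List with `list_name`, `m_genes`, `observed_snps`,
#'   `n_resamples`, `null_counts` (quantile summary), `empirical_p`,
#'   `p_type`, `seed`.
#' @export
resampling_empirical_p <- function(gene_list, universe = unique(map$gene_id),
                                   map, sig_snp_ids, n_resamples = 10000L,
                                   seed = 1L,
                                   p_type = c("add_one", "plug_in"),
                                   match_snp_count = FALSE,
                                   list_name = "gene_list") {
  p_type <- match.arg(p_type)
  stopifnot(n_resamples >= 1L)
  in_universe <- intersect(gene_list, universe)
  missing <- setdiff(gene_list, universe)
  if (length(missing))
    warning(length(missing), " listed gene(s) absent from the universe")
  m <- length(in_universe)
  if (m == 0L) stop("no listed gene is in the universe")

  observed <- count_list_snps(in_universe, map, sig_snp_ids)

  # per-gene tallies over the universe
  map_u <- map[map$gene_id %in% universe, , drop = FALSE]
  sig_by_gene <- integer(length(universe)); names(sig_by_gene) <- universe
  is_sig <- map_u$snp_id %in% sig_snp_ids
  if (any(is_sig)) {
    t <- table(factor(map_u$gene_id[is_sig], levels = universe))
    sig_by_gene[] <- as.integer(t)
  }
  # SNPs mapping to >1 gene force set-union counting; otherwise counts add
  sig_multi <- any(duplicated(map_u$snp_id[is_sig]))
  gene_sig_snps <- if (sig_multi)
    split(map_u$snp_id[is_sig], factor(map_u$gene_id[is_sig], levels = universe))

  n_univ <- length(universe)
  set.seed(seed)
  draw_idx <- if (match_snp_count) {
    snp_by_gene <- table(factor(map_u$gene_id, levels = universe))
    bins <- pmin(as.integer(snp_by_gene), 5L)
    list_bins <- table(factor(pmin(as.integer(snp_by_gene[in_universe]), 5L),
                              levels = 1:5))
    bin_idx <- split(seq_len(n_univ), bins)
    function() {
      unlist(lapply(1:5, function(b) {
        need <- as.integer(list_bins[b])
        if (!need) return(integer(0L))
        pool <- bin_idx[[as.character(b)]]
        if (length(pool) < need)
          stop("stratum with ", length(pool), " genes cannot supply ", need)
        pool[sample.int(length(pool), need)]
      }), use.names = FALSE)
    }
  } else {
    function() sample.int(n_univ, m)
  }

  counts <- integer(n_resamples)
  for (r in seq_len(n_resamples)) {
    idx <- draw_idx()
    counts[r] <- if (sig_multi)
      length(unique(unlist(gene_sig_snps[idx], use.names = FALSE)))
    else sum(sig_by_gene[idx])
  }
  b <- sum(counts >= observed)
  p <- if (p_type == "add_one") (1 + b) / (1 + n_resamples) else b / n_resamples
  list(list_name = list_name, m_genes = m, observed_snps = observed,
       n_resamples = as.integer(n_resamples),
       null_counts = stats::quantile(counts, c(0, 0.25, 0.5, 0.75, 1)),
       empirical_p = p, p_type = p_type, seed = as.integer(seed))
}

#' Expected interacting-gene count from a background rate
#'
#' Given `background_interacting` genes with a property (e.g. known
#' interaction with viral products) among `background_total` SNP-covered
#' genes, the expected number with the property in a set of `n_genes`
#' random genes is `n_genes * background_interacting / background_total`.
#'
#' @param n_genes Size of the gene set.
#' @param background_interacting Genes with the property in the background.
#' @param background_total Background size.
#' @return Expected count (real).
#' @examples
#' expected_interactions(23, 1916, 15280)  # 2.88
#' @export
expected_interactions <- function(n_genes, background_interacting,
                                  background_total) {
  stopifnot(background_total > 0,
            background_interacting >= 0,
            background_interacting <= background_total)
  n_genes * background_interacting / background_total
}

#' Goodness-of-fit test for an interacting-gene excess
#'
#' One-degree-of-freedom chi-squared comparing the observed split
#' (interacting, non-interacting) of `n_genes` against the expectation
#' implied by the background rate; upper-tail p.
#'
#' @param n_genes Genes in the set.
#' @param observed_interacting Observed genes with the property.
#' @param background_interacting,background_total Background counts.
#' @return List with `n_genes`, `observed_interacting`, `expected`,
#'   `chi2`, `p` and the background counts.
#' @export
interaction_chisq <- function(n_genes, observed_interacting,
                              background_interacting, background_total) {
  stopifnot(observed_interacting >= 0, observed_interacting <= n_genes)
  expected <- expected_interactions(n_genes, background_interacting,
                                    background_total)
  if (expected <= 0) stop("expected count is zero: no background signal")
  if (expected >= n_genes)
    stop("degenerate expectation: expected >= n_genes")
  chi2 <- (observed_interacting - expected)^2 / expected +
    ((n_genes - observed_interacting) - (n_genes - expected))^2 /
    (n_genes - expected)
  list(n_genes = as.integer(n_genes),
       observed_interacting = as.integer(observed_interacting),
       background_interacting = as.integer(background_interacting),
       background_total = as.integer(background_total),
       expected = expected, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Binomial over-representation of categories in a gene list
#'
#' For every category, compares its frequency in the study list to the
#' reference list by an exact upper-tail binomial test with success
#' probability equal to the reference fraction; a Bonferroni-adjusted
#' column (over the categories actually tested) is included. Categories
#' absent from both lists are skipped with a note.
#'
#' @param list_counts Named integer vector: genes per category in the list.
#' @param list_size Genes in the study list.
#' @param ref_counts Named integer vector: genes per category in the
#'   reference; must cover every category in `list_counts` that has
#'   members.
#' @param ref_size Genes in the reference list.
#' @return Data frame: category, list_count, ref_count, expected, p_value,
#'   p_bonferroni; attribute `skipped` holds categories with no members
#'   anywhere.
#' @export
binomial_overrepresentation <- function(list_counts, list_size,
                                        ref_counts, ref_size) {
  stopifnot(list_size >= 1L, ref_size >= list_size)
  cats <- names(list_counts)
  if (is.null(cats)) stop("list_counts must be named by category")
  skip <- cats[list_counts == 0L &
                 (is.na(ref_counts[cats]) | ref_counts[cats] == 0L)]
  keep <- setdiff(cats, skip)
  absent <- keep[is.na(ref_counts[keep]) | ref_counts[keep] == 0L]
  if (length(absent))
    stop("category absent from reference: ", paste(absent, collapse = ", "))
  pr <- ref_counts[keep] / ref_size
  p <- stats::pbinom(list_counts[keep] - 1L, list_size, pr, lower.tail = FALSE)
  out <- data.frame(category = keep,
                    list_count = as.integer(list_counts[keep]),
                    ref_count = as.integer(ref_counts[keep]),
                    expected = list_size * pr,
                    p_value = as.numeric(p),
                    p_bonferroni = pmin(1, as.numeric(p) * length(keep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skip
  out
}
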