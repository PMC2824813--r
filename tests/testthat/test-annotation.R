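write_bed <- function(lines, name = "genes.bed") {
  path <- file.path(tempdir(), name)
  writeLines(lines, path)
  path
}

test_that("BED6 gene models are read, validated and collapsed by symbol", {
  bed <- write_bed(c("1\t1000\t2000\tGENE1\t0\t+",
                     "1\t1500\t2500\tGENE2\t0\t-",
                     "2\t100\t900\tGENE3\t0\t+"))
  g <- read_gene_models(bed)
  expect_equal(nrow(g), 3L)                 # overlapping genes both kept
  expect_equal(g$start[g$gene_id == "GENE1"], 1000L)
  expect_equal(g$end[g$gene_id == "GENE1"], 2000L)

  expect_error(read_gene_models(write_bed("1\t10\t20\tG\t0\t.", "dot.bed")),
               "strand")

  # transcript rows collapse to the union span
  two <- read_gene_models(write_bed(c("1\t100\t500\tG\t0\t+",
                                      "1\t300\t900\tG\t0\t+"), "tx.bed"))
  expect_equal(nrow(two), 1L)
  expect_equal(two$start, 100L)
  expect_equal(two$end, 900L)
})

test_that("SNP assignment honours the strand-aware upstream boundary", {
  genes <- data.frame(gene_id = "G", chrom = "1", start = 1000L, end = 2000L,
                      strand = "+", stringsAsFactors = FALSE)
  snp <- function(pos) data.frame(snp_id = paste0("s", pos), chrom = "1",
                                  pos = pos, stringsAsFactors = FALSE)
  hits <- function(pos, up, g = genes)
    nrow(assign_snps_to_genes(snp(pos), g, up))
  expect_equal(hits(1001L, 0L), 1L)   # interior
  expect_equal(hits(600L, 500L), 1L)  # 0-based 599 in [500, 2000)
  expect_equal(hits(499L, 500L), 0L)  # just upstream of the window
  expect_equal(hits(2000L, 0L), 1L)   # last base of the span (0-based 1999)
  expect_equal(hits(2001L, 0L), 0L)

  minus <- transform(genes, strand = "-")
  expect_equal(hits(2400L, 500L, minus), 1L)  # upstream is rightward on -
  expect_equal(hits(600L, 500L, minus), 0L)
})

test_that("assignment equals the interval oracle on random placements", {
  set.seed(31)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:15), chrom = sample(c("1", "2"), 15, TRUE),
                      start = sample(0:5000, 15), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(200:1500, 15)
  genes$strand <- sample(c("+", "-"), 15, TRUE)
  snps <- data.frame(snp_id = sprintf("s%03d", 1:200),
                     chrom = sample(c("1", "2"), 200, TRUE),
                     pos = sample(1:7000, 200), stringsAsFactors = FALSE)
  for (up in c(0L, 250L)) {
    got <- assign_snps_to_genes(snps, genes, up)
    ora <- oracle_assign(snps, genes, up)
    expect_equal(paste(got$snp_id, got$gene_id),
                 paste(ora$snp_id, ora$gene_id))
  }
  # monotonicity: widening the window never removes assignments
  a0 <- assign_snps_to_genes(snps, genes, 0L)
  a1 <- assign_snps_to_genes(snps, genes, 1000L)
  expect_true(all(paste(a0$snp_id, a0$gene_id) %in%
                    paste(a1$snp_id, a1$gene_id)))
})

test_that("genic enrichment chi-squared matches the closed 2x2 form", {
  # 10 significant all genic, 100 controls all non-genic
  res <- data.frame(
    snp_id = sprintf("s%03d", 1:210), chrom = "1", pos = 1:210,
    tau = 0.1, p_value = 0.5, maf = 0.25, n_used = 52L, window_n = 200L,
    rank = 0.5, bonferroni_sig = FALSE, rank_sig = FALSE,
    final_sig = rep(c(TRUE, FALSE), c(10, 200)))
  map <- data.frame(snp_id = res$snp_id[1:10], gene_id = "G",
                    rule_used = "tx_plus_500bp")
  gt <- genic_enrichment_test(res, map, scan_config(maf_window = 0.5),
                              k = 10L, seed = 4L)
  tab <- gt$table
  n <- sum(tab)
  chi2 <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 * n /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  expect_equal(gt$chi2, chi2, tolerance = 1e-12)
  expect_lt(gt$p, 0.001)
  expect_equal(unname(tab["significant", "genic"]), 10)
  expect_equal(unname(tab["control", "genic"]), 0)

  # identical genic fractions -> chi2 0, p 1 (all SNPs genic)
  map_all <- data.frame(snp_id = res$snp_id, gene_id = "G",
                        rule_used = "tx_plus_500bp")
  gt0 <- genic_enrichment_test(res, map_all, scan_config(maf_window = 0.5),
                               k = 10L, seed = 4L)
  expect_equal(gt0$chi2, 0)
  expect_equal(gt0$p, 1)

  expect_error(genic_enrichment_test(res, map, scan_config(maf_window = 0.5),
                                     k = 100L, seed = 1L), "smaller k")
})
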