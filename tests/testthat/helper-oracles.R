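# Independent oracles and small fixture builders used across the suite.

# Exhaustive pair-classification Kendall tau-b with tie-corrected normal p.
# Deliberately naive: double loop over pairs, tie groups via table().
oracle_kendall <- function(x, y) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- num + sign(x[i] - x[j]) * sign(y[i] - y[j])
  }
  tx <- as.vector(table(x)); ty <- as.vector(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  v <- (n * (n - 1) * (2 * n + 5) -
          sum(tx * (tx - 1) * (2 * tx + 5)) -
          sum(ty * (ty - 1) * (2 * ty + 5))) / 18 +
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2)) +
    sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  z <- num / sqrt(v)
  list(tau = num / sqrt((n0 - n1) * (n0 - n2)),
       p_value = 2 * pnorm(-abs(z)))
}

# Interval-arithmetic SNP-to-gene assignment oracle (1-based SNP positions,
# 0-based half-open gene spans, strand-aware upstream extension).
oracle_assign <- function(snp_meta, genes, upstream_bp) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    lo <- if (genes$strand[g] == "+")
      max(0L, genes$start[g] - upstream_bp) else genes$start[g]
    hi <- if (genes$strand[g] == "-")
      genes$end[g] + upstream_bp else genes$end[g]
    for (s in seq_len(nrow(snp_meta))) {
      p0 <- snp_meta$pos[s] - 1L
      if (snp_meta$chrom[s] == genes$chrom[g] && p0 >= lo && p0 < hi)
        out[[length(out) + 1L]] <- c(snp_meta$snp_id[s], genes$gene_id[g])
    }
  }
  if (!length(out)) return(data.frame(snp_id = character(), gene_id = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("snp_id", "gene_id")
  df[order(df$gene_id, df$snp_id), , drop = FALSE]
}

write_tmp_tsv <- function(df, dir = tempdir(), name = "tmp.tsv") {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Tiny 4-population panel used by the reader tests.
tiny_panel <- function() {
  data.frame(population = c("p1", "p2", "p3", "p4"),
             country = c("A", "A", "B", "C"),
             n_sampled = c(10L, 12L, 8L, 20L),
             stringsAsFactors = FALSE)
}

tiny_freq_file <- function(freqs = NULL, dir = tempdir()) {
  if (is.null(freqs))
    freqs <- matrix(c(0.1, 0.2, 0.3, 0.4,
                      0.9, 0.8, 0.7, 0.6,
                      0.5, NA, 0.5, 0.5), 3, 4, byrow = TRUE)
  df <- data.frame(snp_id = paste0("s", seq_len(nrow(freqs))),
                   chrom = "1", pos = seq_len(nrow(freqs)) * 100L,
                   coded_allele = "A")
  df <- cbind(df, setNames(as.data.frame(freqs), tiny_panel()$population))
  write_tmp_tsv(df, dir, "freqs.tsv")
}
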