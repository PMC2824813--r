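# Builds a complete, small pipeline input set under `dir` and returns the
# matching configuration list.
pipeline_inputs <- function(dir, n_snps = 300, seed = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_panel(sim_config(n_snps = n_snps, frac_selected = 0.03,
                                   beta = 0.25, seed = seed))
  panel <- sim$panel
  panel$virus_diversity <- as.numeric(sim$env)
  write.table(panel, file.path(dir, "panel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_frequency_matrix(sim$fm, file.path(dir, "freqs.tsv"))
  ann <- simulate_annotation(sim, n_genes = 40, genic_fraction = 0.6,
                             seed = seed)
  bed <- with(ann$genes, paste(chrom, start, end, gene_id, 0, strand,
                               sep = "\t"))
  writeLines(bed, file.path(dir, "genes.bed"))
  writeLines(ann$lists$enriched, file.path(dir, "enriched.txt"))
  writeLines(ann$lists$control, file.path(dir, "control.txt"))
  env_c <- sim$truth$env_country
  set.seed(seed)
  climate <- data.frame(country = names(env_c), tmin = rnorm(21),
                        tmax = rnorm(21) + 20, sw_flux = runif(21, 100, 250))
  write.table(climate, file.path(dir, "climate.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(
    inputs = list(panel = file.path(dir, "panel.tsv"),
                  frequency = file.path(dir, "freqs.tsv"),
                  genes = file.path(dir, "genes.bed"),
                  climate = file.path(dir, "climate.tsv"),
                  gene_lists = list(enriched = file.path(dir, "enriched.txt"),
                                    control = file.path(dir, "control.txt"))),
    scan = list(alpha = 0.05, min_window = 30),
    enrichment = list(n_resamples = 200),
    upstream_bp = 0,
    genic_k = 2,
    seed = seed)
}
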