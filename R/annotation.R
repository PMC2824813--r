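#' Read gene models from a BED6 file
#'
#' BED coordinates are 0-based, half-open; they are stored as such.
#' Strand is mandatory because the upstream extension used for SNP
#' assignment is strand-aware. Multiple rows sharing a symbol (e.g.
#' transcripts) are collapsed to the union span per (symbol, chrom,
#' strand), since downstream analyses count genes, not transcripts.
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score,
#'   strand); the score column is ignored.
#' @return Data frame with columns gene_id, chrom, start, end, strand.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr)) return(data.frame(gene_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character()))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("gene model without strand: ",
         paste(utils::head(gr$name[strand == "*"], 5L), collapse = ", "))
  df <- data.frame(gene_id = as.character(gr$name),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                   end = GenomicRanges::end(gr),
                   strand = strand, stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("gene model with start >= end")
  # collapse duplicate symbols to union spans
  key <- paste(df$gene_id, df$chrom, df$strand, sep = "\r")
  if (anyDuplicated(key)) {
    df <- do.call(rbind, lapply(split(df, key), function(g) {
      g$start[1L] <- min(g$start); g$end[1L] <- max(g$end); g[1L, ]
    }))
    rownames(df) <- NULL
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  ambig <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(ambig))
    warning("symbol(s) on multiple chromosomes/strands kept as separate rows: ",
            paste(ambig, collapse = ", "))
  df
}

#' Assign SNPs to genes with a strand-aware upstream window
#'
#' A SNP at 1-based position P belongs to a gene if its 0-based coordinate
#' P-1 falls within the transcribed span extended by `upstream_bp`
#' basepairs upstream of the transcription start site: `[start -
#' upstream_bp, end)` on the + strand, `[start, end + upstream_bp)` on the
#' - strand (extended starts clamped at 0). The conventional windows are
#' 500 bp for gene-level tallies and 25 kb for network-style mapping. A SNP
#' may map to several overlapping genes.
#'
#' @param snp_meta Data frame with columns snp_id, chrom, pos (1-based).
#' @param genes Gene models from [read_gene_models()].
#' @param upstream_bp Upstream window size in basepairs (>= 0).
#' @return Data frame (snp_id, gene_id, rule_used), one row per
#'   (SNP, gene) pair, ordered by gene then SNP.
#' @export
assign_snps_to_genes <- function(snp_meta, genes, upstream_bp = 500L) {
  stopifnot(upstream_bp >= 0)
  rule <- sprintf("tx_plus_%s", format_bp(upstream_bp))
  if (!nrow(genes) || !nrow(snp_meta))
    return(data.frame(snp_id = character(), gene_id = character(),
                      rule_used = character()))
  shared <- intersect(unique(snp_meta$chrom), unique(genes$chrom))
  if (!length(shared))
    warning("no chromosome names shared between SNPs and gene models")

  ext_start <- ifelse(genes$strand == "+",
                      pmax(0L, genes$start - upstream_bp), genes$start)
  ext_end <- ifelse(genes$strand == "-", genes$end + upstream_bp, genes$end)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(ext_start + 1L, ext_end))
  sgr <- GenomicRanges::GRanges(snp_meta$chrom,
                                IRanges::IRanges(snp_meta$pos, width = 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(sgr, ggr))
  out <- data.frame(snp_id = snp_meta$snp_id[S4Vectors::queryHits(ov)],
                    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
                    rule_used = rep(rule, length(ov)), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

format_bp <- function(bp) {
  if (bp %% 1000 == 0 && bp > 0) paste0(bp / 1000, "kb") else paste0(bp, "bp")
}

#' Genic-location enrichment of significant SNPs
#'
#' Tests whether significant SNPs fall inside genic regions more often than
#' a control set of MAF-matched non-significant SNPs. For each significant
#' SNP, `k` controls are sampled without replacement from the
#' non-significant SNPs within `maf_window` of its MAF; the resulting 2x2
#' table (genic/non-genic x significant/control) is tested by Pearson's
#' chi-squared with 1 df and no continuity correction.
#'
#' @param results Scan results with `final_sig` filled.
#' @param map SNP-gene map from [assign_snps_to_genes()]; a SNP is genic if
#'   it maps to at least one gene.
#' @param cfg A [scan_config()] (provides `maf_window`).
#' @param k Controls sampled per significant SNP (default 10).
#' @param seed Integer seed for control sampling.
#' @return List with `table` (2x2), `chi2`, `p`, `k`, `seed`.
#' @export
genic_enrichment_test <- function(results, map, cfg = scan_config(),
                                  k = 10L, seed = 1L) {
  sig <- results[which(results$final_sig), , drop = FALSE]
  non <- results[which(!results$final_sig), , drop = FALSE]
  if (!nrow(sig)) stop("no significant SNPs")
  set.seed(seed)
  taken <- character(0L)
  controls <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    pool <- non$snp_id[abs(non$maf - sig$maf[i]) <= cfg$maf_window]
    pool <- setdiff(pool, taken)
    if (length(pool) < k)
      stop("not enough MAF-matched controls; try a smaller k")
    controls[[i]] <- sample(pool, k)
    taken <- c(taken, controls[[i]])
  }
  controls <- unlist(controls)
  genic <- unique(map$snp_id)
  tab <- rbind(significant = c(genic = sum(sig$snp_id %in% genic),
                               non_genic = sum(!sig$snp_id %in% genic)),
               control = c(sum(controls %in% genic),
                           sum(!controls %in% genic)))
  colnames(tab) <- c("genic", "non_genic")
  if (any(colSums(tab) == 0L)) {
    chi2 <- 0; p <- 1   # degenerate margin: no information
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  list(table = tab, chi2 = chi2, p = p, k = as.integer(k),
       seed = as.integer(seed))
}
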