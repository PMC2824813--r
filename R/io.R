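#' Read a population panel table
#'
#' Reads a tab-delimited panel description with one row per sampled
#' population. The file must carry a header with at least the columns
#' `population`, `country` and `n_sampled`; any additional columns (for
#' example a pre-computed pathogen diversity per country) are retained
#' untouched.
#'
#' @param path Path to a UTF-8, tab-delimited file.
#' @return A data frame with one row per population, in file order.
#'   Duplicate population labels are rejected.
#' @export
read_population_table <- function(path) {
  df <- read_tsv_checked(path, required = c("population", "country", "n_sampled"))
  df$population <- as.character(df$population)
  df$country <- as.character(df$country)
  df$n_sampled <- as.integer(df$n_sampled)
  if (anyDuplicated(df$population)) {
    dup <- unique(df$population[duplicated(df$population)])
    stop("duplicate population label(s): ", paste(dup, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(is.na(df$n_sampled)) || any(df$n_sampled < 1L))
      stop("n_sampled must be a positive integer for every population")
    if (any(!nzchar(df$country)) || any(is.na(df$country)))
      stop("country must be non-empty for every population")
  }
  df
}

#' Packaged HGDP-CEPH panel fixture
#'
#' The 52-population worldwide panel with its per-country virus diversity
#' (number of virus species/genera/families naturally transmitted in the
#' country). Shipped so that country-level diversity can be used directly
#' when no pathogen presence/absence matrix is available.
#'
#' @return A data frame with columns `population`, `country`, `n_sampled`
#'   and `virus_diversity`.
#' @export
hgdp_panel <- function() {
  read_population_table(system.file("extdata", "hgdp_panel.tsv",
                                    package = "pathosel", mustWork = TRUE))
}

#' Read a pathogen presence/absence matrix
#'
#' Rows are pathogen taxa (species, genus or family labels, treated as
#' opaque unique keys), columns are countries; cells are 1 if the pathogen
#' is naturally transmitted in the country and 0 otherwise. Curation rules
#' (exclusion of tourism-imported cases, eradicated species recorded as
#' present) are the matrix curator's responsibility.
#'
#' @param path Tab-delimited file; first column `pathogen`, then one 0/1
#'   column per country.
#' @return An integer matrix with pathogen rownames and country colnames.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L || names(df)[1L] != "pathogen")
    stop("presence matrix must have a first column named 'pathogen'")
  pathogens <- as.character(df[[1L]])
  countries <- names(df)[-1L]
  if (anyDuplicated(pathogens)) stop("duplicate pathogen label(s)")
  if (anyDuplicated(countries)) stop("duplicate country column(s)")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) > 0L) {
    if (any(is.na(m)) || !all(m %in% c(0, 1)))
      stop("presence matrix cells must all be 0 or 1")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- pathogens
  m
}

#' Pathogen diversity per country
#'
#' Counts, for every country, the number of pathogen taxa recorded as
#' naturally transmitted there (column sums of the presence matrix).
#'
#' @param m Presence matrix as returned by [read_presence_matrix()].
#' @return Named integer vector, one count per country.
#' @export
compute_diversity <- function(m) {
  if (!is.matrix(m)) stop("'m' must be a matrix")
  if (length(m) && (any(is.na(m)) || !all(m %in% c(0L, 1L))))
    stop("presence matrix cells must all be 0 or 1")
  res <- colSums(m)
  storage.mode(res) <- "integer"
  res
}

#' Broadcast country-level values to populations
#'
#' Pathogen diversity and climate are measured per country; populations of
#' the same country therefore carry identical values. This deliberate tie
#' structure is preserved throughout all rank-correlation analyses.
#'
#' @param panel Panel data frame with `population` and `country` columns.
#' @param country_values Named numeric vector, one value per country.
#' @param name Label of the environmental variable.
#' @return Named numeric vector in panel order (names are population
#'   labels) with attribute `var_name`.
#' @export
broadcast_to_populations <- function(panel, country_values, name = "env") {
  missing <- setdiff(unique(panel$country), names(country_values))
  if (length(missing))
    stop("no value for country: ", paste(missing, collapse = ", "))
  v <- as.numeric(country_values[panel$country])
  names(v) <- panel$population
  attr(v, "var_name") <- name
  v
}

#' Read a SNP-by-population allele frequency matrix
#'
#' Expects a tab-delimited file whose first four columns are `snp_id`,
#' `chrom`, `pos` (1-based basepair) and `coded_allele`, followed by one
#' numeric column per population. Cells are coded-allele frequencies in
#' \[0,1\]; `NA` marks populations without a frequency estimate for the SNP.
#'
#' @param path Path to the TSV file.
#' @param panel Optional panel data frame; if given, the frequency columns
#'   must match `panel$population` exactly (order included).
#' @return An object of class `freq_matrix`: list with `snp_meta` (data
#'   frame: snp_id, chrom, pos, coded_allele) and `freqs` (numeric matrix,
#'   SNPs x populations).
#' @export
read_frequency_matrix <- function(path, panel = NULL) {
  df <- read_tsv_checked(path, required = c("snp_id", "chrom", "pos", "coded_allele"))
  meta_cols <- c("snp_id", "chrom", "pos", "coded_allele")
  pops <- setdiff(names(df), meta_cols)
  if (length(pops) < 1L) stop("no population columns found")
  if (!is.null(panel) && !identical(pops, panel$population))
    stop("frequency matrix population columns do not match the panel")
  meta <- df[meta_cols]
  meta$snp_id <- as.character(meta$snp_id)
  meta$chrom <- as.character(meta$chrom)
  meta$pos <- as.integer(meta$pos)
  if (anyDuplicated(meta$snp_id)) stop("duplicate snp_id in frequency matrix")
  if (any(is.na(meta$pos)) || any(meta$pos < 0L))
    stop("SNP positions must be nonnegative integers")
  freqs <- as.matrix(df[pops])
  storage.mode(freqs) <- "double"
  bad <- which(!is.na(freqs) & (freqs < 0 | freqs > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("allele frequency outside [0,1] for SNP ",
         paste(unique(meta$snp_id[bad[, 1L]]), collapse = ", "))
  rownames(freqs) <- meta$snp_id
  freq_matrix(meta, freqs)
}

#' Construct a frequency matrix object
#'
#' @param snp_meta Data frame with columns snp_id, chrom, pos, coded_allele.
#' @param freqs Numeric matrix (SNPs x populations) of coded-allele
#'   frequencies; rownames must equal `snp_meta$snp_id`.
#' @return `freq_matrix` object.
#' @export
freq_matrix <- function(snp_meta, freqs) {
  stopifnot(nrow(snp_meta) == nrow(freqs))
  structure(list(snp_meta = snp_meta, freqs = freqs), class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("<freq_matrix> ", nrow(x$freqs), " SNPs x ", ncol(x$freqs),
      " populations (", sum(is.na(x$freqs)), " missing cells)\n", sep = "")
  invisible(x)
}

#' Write a frequency matrix to TSV
#'
#' Inverse of [read_frequency_matrix()]; numeric cells are written with 15
#' significant digits so that a read/write round trip is lossless well
#' beyond measurement precision.
#'
#' @param fm `freq_matrix` object.
#' @param path Output path.
#' @export
write_frequency_matrix <- function(fm, path) {
  out <- cbind(fm$snp_meta,
               as.data.frame(fm$freqs, check.names = FALSE))
  write_tsv(out, path)
}

#' Read a country-level climate table
#'
#' One row per country with annual mean daily minimum temperature (`tmin`,
#' degrees C), maximum temperature (`tmax`, degrees C) and net shortwave
#' radiation flux (`sw_flux`, W/m2), already averaged over the reference
#' years; the averaging itself happens upstream of this package.
#'
#' @param path Path to the TSV file (columns country, tmin, tmax, sw_flux).
#' @return Data frame with one validated row per country.
#' @export
read_climate_table <- function(path) {
  df <- read_tsv_checked(path, required = c("country", "tmin", "tmax", "sw_flux"))
  df$country <- as.character(df$country)
  if (anyDuplicated(df$country)) stop("duplicate country in climate table")
  for (v in c("tmin", "tmax", "sw_flux")) df[[v]] <- as.numeric(df[[v]])
  bad <- which(df$tmin > df$tmax)
  if (length(bad))
    stop("tmin > tmax for country: ", paste(df$country[bad], collapse = ", "))
  df
}

# -- internal helpers ---------------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  # fixed 15-digit formatting keeps reruns byte-identical across platforms
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- NA
    trimws(out)
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
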