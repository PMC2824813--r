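Package: pathosel
Title: Genome-Wide Scans for Pathogen-Driven Selection from Population
    Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate targets of pathogen-driven selection by rank
    correlation between per-population allele frequencies and an
    environmental measure of pathogen pressure (e.g. the number of virus
    species transmitted per country). Provides a tie-corrected Kendall
    tau-b scan with an empirical null based on percentile ranks among
    minor-allele-frequency matched SNPs, SNP-to-gene assignment with
    strand-aware upstream windows, gene-list enrichment by gene
    resampling, interaction-count and binomial over-representation
    statistics, a climate confounder screen, and a hierarchical
    Balding-Nichols simulator of structured allele-frequency panels with
    spiked environment-associated loci for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
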