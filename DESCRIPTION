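Package: radpanel
Title: Dosage Genomics for Radiation Mutagenesis Panels in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of genome- and transcriptome re-sequencing data from
    irradiated allopolyploid mutagenesis panels (Brassica napus, AACC).
    Quantifies homoeologue dosage from gene-level read counts (RPKM),
    renders genome display tile plots in CMYK colour space, calls segmental
    and whole-chromosome copy number variants and homoeologous exchanges,
    matches reciprocal deletion/duplication events between sibling plants,
    summarizes dose-response tables and saturation estimates, filters
    small-variant calls (control subtraction, recurrence, variant-allele
    read depth tiers) with a simplified coding-consequence classifier,
    genotypes copy number from inter-homoeologue polymorphism peak signals,
    and links gene dosage to seed oil fatty-acid phenotypes. Includes a
    synthetic irradiated-panel generator so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
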