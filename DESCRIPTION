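Package: ipsomatic
Title: Somatic SNV Selection and Q-FISH Telomere Quantification for iPS
    Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-calling selection of culture-acquired somatic single
    nucleotide variants (SNVs) in induced pluripotent stem (iPS) cell
    exomes: stringent site-quality hard filters, genotype-class-specific
    allelic-depth rules, exclusion of variants inside large structural
    alterations (copy-neutral LOH, deletions), mutation accounting,
    base-change spectra and per-population-doubling mutation rates.
    Also quantifies telomere length from quantitative fluorescence in
    situ hybridization (Q-FISH) per-telomere intensity tables via
    median telomere fluorescence intensity ratios against a calibrated
    control line, plus small culture metrics (reprogramming efficiency,
    post-irradiation survival fractions). A seeded synthetic-data
    generator emulates a parental fibroblast line plus derived iPS
    clones so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
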