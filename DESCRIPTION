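Package: duplexr
Title: Duplex Consensus Sequencing Simulation and Ultra-Rare Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ultra-rare de novo substitutions detected by
    duplex consensus sequencing of a targeted coding region. Includes a
    synthetic paired-read generator with double-stranded barcode families,
    strand-asymmetric DNA-damage artifacts, PCR jackpot errors and spike-in
    dilution series; single-strand (SSCS) and duplex (DCS) consensus calling;
    tiered substitution calling with SNP masking and coverage filters;
    mutation-frequency estimation with exact Poisson intervals and stratified
    group tests; pyrimidine-centred 6-class and 96-trinucleotide mutational
    spectra with bootstrap cosine-similarity references; and Nei-Gojobori
    dN/dS selection analysis against a spectrum-preserving randomization null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
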