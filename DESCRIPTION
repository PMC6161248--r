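Package: semiquantr
Title: Targeted LC-MS/MS Semiquantification and Quality Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for targeted liquid
    chromatography tandem mass spectrometry (LC-MS/MS) semiquantification
    of polar metabolites. Parses vendor-style flat-text quantification
    exports into tidy injection tables, fits weighted and log-log
    calibration curves with LLOQ/ULOQ determination and carryover checks,
    applies the molecular-weight / process-efficiency / dilution /
    matrix-specific correction chain that converts raw ppb readings into
    micromolar concentrations, computes EMA-style bioanalytical validation
    statistics (accuracy, precision, recovery, matrix effect, stability),
    manages batch layouts and quality-control drift surveillance against a
    QC history database, and estimates population reference medians with
    95% credibility intervals from lot-structured QC histories via a
    hierarchical log-normal Gibbs sampler. Ships a curated 102-metabolite
    healthy-adult serum reference panel and a fully seeded synthetic-data
    generator so every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    lme4,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
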