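Package: ubicore
Title: Two-Parameter Core Microbiome Election and Cohort Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for electing core and "minor core" taxa from 16S taxonomic
    count tables using a two-parameter (abundance cutoff, ubiquity cutoff)
    model. Provides ubiquity-versus-abundance survival curves, binomial
    detection qualification for low-abundance presence calls,
    variance-versus-abundance summaries of taxon stability, body-region core
    composition by averaging or multiplying habitat ubiquities, and an
    abundance-weighted Kolmogorov-Smirnov (AWKS) statistic with a donor/read
    bootstrap null distribution for comparing the microbiota of two cohorts.
    Includes a seeded synthetic cohort generator with planted core, minor-core
    and sporadic taxa for testing and power studies, ggplot2 renderings of
    Ub-Ab, Var-Ab and U-U representations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
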