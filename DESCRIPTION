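Package: metsel
Title: Multi-Trait Selection Indices for Multi-Environment Wheat Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-trait truncation selection in plant breeding
    programs evaluated across multi-environment trials. Simulates balanced
    genotype-by-environment phenotype data with a known genetic architecture,
    estimates genetic and phenotypic covariance matrices by balanced-ANOVA
    method of moments, implements the Smith linear phenotypic selection index
    (LPSI) and the Kempthorne-Nordskog null-restricted index (RLPSI) with
    Mallard predetermined-proportional-gain constraints, sweeps large grids
    of economic weights with ANOVA-based weight comparison, and performs
    truncation selection of superior genotypes with cross-scenario
    consistency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
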