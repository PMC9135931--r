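Package: lipidaging
Title: Fatty-Acid Compositional Analysis of Human Brain Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing gas-chromatography fatty-acid profiles
    (mol% compositions) of human brain regions across aging. Computes
    membrane lipid indexes (average chain length, double bond index,
    peroxidizability index, saturated/unsaturated class totals), surrogate
    desaturase, elongase and peroxisomal beta-oxidation activities from
    product/substrate ratios, middle-aged versus elderly group comparisons
    with Benjamini-Hochberg false-discovery-rate control, Spearman
    age-continuum correlation analysis, and cross-region correlation
    matrices. Includes a seeded logistic-normal simulator that generates
    synthetic cohorts with the compositional closure and mean/SEM structure
    of published regional brain fatty-acid tables, and a transcribed
    reference table of 13 regions by 2 age groups as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
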