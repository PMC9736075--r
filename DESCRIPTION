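Package: roaddust
Title: Trace-Metal Contamination, Bioaccessibility, and Probabilistic
    Health Risk Assessment for Road Dust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing trace-metal contamination of urban road
    dust and the resulting human health risk. Computes geochemical
    contamination indices (geoaccumulation index, improved Nemerow index,
    Hakanson potential ecological risk), sequential-extraction speciation
    accounting, in vitro gastrointestinal (IVG) oral bioaccessibility, and
    a bioaccessibility-adjusted USEPA-style exposure model (average daily
    dose, hazard quotient/index, incremental lifetime cancer risk) for
    children, adult women, and adult men, with a Monte Carlo layer for
    uncertainty and rank-correlation sensitivity analysis. Includes a
    synthetic-data generator that emulates the per-zone summary statistics
    of a published Guangzhou road-dust survey so the full pipeline is
    testable without the unpublished raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
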