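Package: fluctnet
Title: Dynamic Functional Network Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved analysis of parcellated resting-state BOLD time
    series, built around the dynamics thought to break down in Dementia with
    Lewy bodies: multiplication-of-temporal-derivatives (MTD) sliding-window
    connectivity, temporal similarity statistics (local and global pattern
    similarity), time-resolved community structure with participation
    coefficient and module-degree z-score, cartographic profiles, k-means
    segregated-state occupancy, Hungarian label matching and regional modular
    flexibility, an EZ-style closed-form drift-diffusion fit to summary
    statistics of sustained-attention performance, covariate-adjusted
    permutation inference with FDR control, and spatial correlation of regional
    group differences with receptor gene-expression maps. Includes a fully
    seeded synthetic-cohort generator (hidden-state modular time series,
    motion traces, diffusion reaction times, planted expression maps) so the
    entire pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    signal,
    jsonlite,
    yaml,
    withr,
    readr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
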