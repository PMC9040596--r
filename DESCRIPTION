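Package: soilcosm
Title: Simulation and Quantification of Soil Microcosm Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how species-rich soil bacterial communities
    assemble and propagate in microcosm culturing systems. Implements a
    stochastic-inoculum, carbon-limited multi-taxon Monod growth simulator
    (deterministic growth, stochastic sampling), a serial growth/dilution
    cycle engine, amplicon-based strain quantification with 16S rRNA operon
    copy-number correction and flow-cytometry anchored absolute abundances,
    threshold-gated flow cytometry cell counting with background subtraction,
    community summary metrics (depth-normalized richness, Shannon diversity,
    Bray-Curtis distances, replicate-to-centroid variability), and carbon
    budget calculators. Includes seeded synthetic-data generators for
    long-tailed rank-abundance pools, amplicon read sets with embedded strain
    identifiers, and flow-cytometry event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
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
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
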