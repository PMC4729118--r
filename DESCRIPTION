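Package: horizonbed
Title: Horizon Charts for Genomic Signal Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Renders multi-sample genomic signal (read depth and other
    BED/BedGraph-encoded metrics) as compact, band-collapsed horizon track
    charts. Provides 0-based half-open genomic coordinate handling, BED and
    BedGraph parsing with validation, per-pixel interval binning, an
    invertible horizon band decomposition (banding, mirroring, collapsing),
    deterministic SVG rendering, pluggable data sources (in-memory BED files,
    a simplified tabix-style linear index with seek-and-scan region queries,
    and a small RESTful region-query server), plus a synthetic multi-sample
    coverage simulator for quality-control demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    callr,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
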