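Package: trackqc
Title: Quality Control and Visualization for Time-Lapse Cell Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inspecting and quality-controlling object-tracking
    output from time-lapse microscopy. Reads tracking databases in the
    simple three-table schema produced by high-content image-analysis
    pipelines (an image table, an object table, and a parent-child
    relationship table; SQLite or CSV), builds directed lineage graphs,
    flags topological aberrations that suggest segmentation or tracking
    errors (transient split/re-merge loops, merge/split crossings, and
    spurious short "singleton" tracks), computes track-length statistics,
    prunes singletons into derived relationship tables persisted alongside
    the originals, summarizes per-object features into per-timepoint
    heatmap matrices, and renders XYT trajectory plots, lineage trees,
    synchrograms, and feature heatmaps. A ground-truthed synthetic
    tracked-nuclei simulator makes every component testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    DBI,
    RSQLite,
    tiff,
    png,
    yaml,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
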