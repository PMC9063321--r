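Package: evodfnc
Title: Multiframe Evolving Dynamic Functional Network Connectivity Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes time-varying whole-brain functional network
    connectivity as a small set of multiframe "movie-style" evolving
    connectivity motifs (EVOdFNCs). Computes tapered sliding-window dynamic
    functional network connectivity from network timecourses, embeds the
    windowed trajectories into the plane with multi-run averaged UMAP,
    distills linear trajectory exemplars from local linearizations of the
    embedded curves, lifts each exemplar back to connectivity space by
    nearest-neighbor averaging, and scores observed dynamics against the
    lifted motifs (representational importance, meta-state occupancy).
    Includes a time-blind snapshot-state k-means baseline, covariate-adjusted
    group and symptom regression models with multiple-comparison correction,
    and a synthetic-cohort generator with planted evolving motifs for
    end-to-end validation.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    optparse,
    readr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
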