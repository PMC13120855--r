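Package: dyadica
Title: Quantification of Dyadic Social Behavior in Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying social behavior of interacting flies from
    frame-indexed action-bout annotations: ethogram construction with
    first-transition edges, sliding-window expressivity traces, courtship and
    aggression metrics (time fractions, event rates, latencies, cumulative
    event curves), social indices (target preference, dominance
    one-sidedness, ovipositor-extrusion normalization, receptivity, priming
    concordance), photostimulation-locked analyses (segment aggregation,
    onset-aligned courtship suppression curves, penetrance and expressivity),
    courtship-song peak refinement and pulse/clack train segmentation,
    odor place-preference occupancy from video frames, and the accompanying
    nonparametric statistical toolkit (rank tests, Dunn letter groupings,
    Benjamini-Hochberg correction, Cohen's d, Tukey outlier fences). A
    semi-Markov behavior simulator with known ground truth generates bout
    tables, song waveforms, and arena walks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
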