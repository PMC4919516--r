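Package: aobtune
Title: Stimulus-Response Tuning Analysis for Accessory Olfactory Bulb
    Single-Unit Recordings
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured single-unit recordings
    from chemosensory stimulation experiments: peristimulus time histograms,
    stimulus-evoked firing-rate changes (delta-R) with t-test plus rate-floor
    significance calling, per-cell tuning normalization and category/overlap
    summaries, consensus clustering of tuning curves (random-k k-means
    co-assignment followed by mean-shift on the similarity matrix) with
    nonmetric multidimensional scaling, and a d-prime discriminability index
    with a shuffled-population Kruskal-Wallis significance test. Includes a
    seeded Poisson spike-train simulator with known ground-truth tuning so
    every stage has a parameter-recovery oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
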