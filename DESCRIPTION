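Package: smcquant
Title: Quantification of Calcium Release Events and Contraction in Smooth Muscle Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of vascular smooth-muscle-cell function from
    fluorescence image sequences. Detects active regions of interest above statistical
    noise in calcium-indicator (Fluo-4) recordings, normalizes traces to F/F0, detects
    and classifies calcium release events into main and secondary peaks, and measures
    half-maximum kinetic parameters (time to peak, decay, duration). Segments and
    tracks calcein-loaded cells across pre-stimulus, post-control and post-drug states
    to measure per-cell contraction as relative surface-area change. Compares
    population histograms of any measurement with a total-variation divergence
    statistic (D-metric) and its low/moderate/high categorization. Includes a seeded
    synthetic-data generator producing ground-truth-annotated traces and image stacks
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
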