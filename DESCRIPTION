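Package: beatsync
Title: Period-Matching Analysis of Bouncing and Clapping to Music
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for full-body sensorimotor synchronization
    experiments in which participants bounce or clap along with music and
    metronomes while wearing a 3-axis accelerometer. Extracts movement
    events (maximal knee flexion, hand impacts) from acceleration traces,
    determines the produced metrical level from the power spectrum, scores
    period-matching with segmented circular statistics (Rayleigh tests,
    circular variance), classifies trials and participants as normal or
    poor synchronizers, analyzes self-paced motor production, and profiles
    poor synchronizers by clustering condition-wise success proportions.
    Includes a synthetic-cohort generator that emulates the study design so
    that every stage of the pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    signal,
    cluster,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
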