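Package: patsep
Title: Spike-Train Pattern Separation and Behavioral Analysis for
    Dentate Gyrus Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify pattern separation by single dentate gyrus
    granule cells from input/output spike trains, following the
    slice-stimulation paradigm in which five correlated 10 Hz Poisson input
    trains are delivered repeatedly and the evoked output trains are
    compared pairwise with the inputs.  Implements binned spike-count
    similarity metrics (Pearson correlation, normalized dot product,
    scaling factor), spike-pattern statistics (firing rate, burst
    probability, compactness, occupancy, dispersion), ANCOVA and t-test
    based group inference, behavioral analyses for open-field and
    novel-object tasks (locomotion, zone dwell times, discrimination
    index), immediate-early-gene cell-density summaries, and a calibrated
    synthetic-data generator (correlated Poisson trains by mother-train
    thinning, simulated granule-cell responders, arena trajectories,
    behavioral cohorts) so the whole pipeline runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
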