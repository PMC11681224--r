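Package: sprintvision
Title: Video-Based Instantaneous Speed Tracking for 100-m Sprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computer-vision pipeline for measuring the instantaneous
    running speed of a 100-m sprinter from four synchronized side-view
    cameras. Detects the athlete per frame by background subtraction,
    thresholding, median-filter denoising and connected-component centroid
    extraction; maps pixel positions to track metres with a two-marker
    linear calibration per camera; fuses the four 25-m segment tracks into
    one 0-100 m position series with gap interpolation and smoothing;
    derives windowed instantaneous speeds and mean speeds per 10-m subtask
    (V1-V10). Includes concurrent-validity statistics (Pearson correlation
    with agreement categories, Bland-Altman limits of agreement), cohort
    summaries, and a fully ground-truthed synthetic multi-camera sprint
    generator so every stage is testable without real footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
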