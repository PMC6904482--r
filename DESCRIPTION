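Package: reprocad
Title: Reproducibility Evaluation for Lesion-Detection CAD on Paired Exams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates computer-aided detection (CAD) of lung nodules and
    masses on paired chest radiographs of the same patient. Matches detector
    bounding boxes to ground-truth lesions under an intersection-over-union
    hit criterion, builds free-response ROC (FROC) curves, selects operating
    thresholds at target false-positive rates, computes the JAFROC figure of
    merit with a resampled confidence interval, and quantifies between-exam
    reproducibility with percent positive agreement (PPA) and Chamberlain's
    percent positive agreement (CPPA) aggregated over a set of operating
    points. Includes a statistically controlled simulator of paired detector
    output with known sensitivity and between-exam correlation, a toy image
    renderer plus difference-of-Gaussians blob detector for end-to-end
    exercises, and report generation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
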