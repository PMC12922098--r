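Package: oknflow
Title: Optokinetic Nystagmus Detection from Eye-Camera Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts horizontal eye-displacement traces from infrared
    eye-camera video by two routes - binary centroid pupil tracking and
    phase-based motion microscopy (a complex steerable pyramid
    decomposition followed by an amplitude-weighted least-squares phase
    flow solve) - and detects optokinetic nystagmus (OKN), the sawtooth
    eye movement evoked by a drifting stimulus, in any 1-D displacement
    trace.  Per-trial decisions from gaze, centroid and phase signals are
    combined across eyes and through a two-stage fallback (STEP) scheme,
    and scored against ground-truth labels with confusion matrices and
    the Matthews correlation coefficient.  Includes a seeded synthetic
    eye-video and gaze-trace generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
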