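Package: cpetsound
Title: Tracheal Breath-Sound Analysis for Cardiopulmonary Exercise Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate exercise-capacity indices from tracheal breath
    sounds recorded during an incremental cycle-ergometer cardiopulmonary
    exercise test (CPET). The pipeline band-pass filters and resamples the
    raw microphone signal, suppresses stationary ambient noise and motion
    spikes, segments breath cycles from the log-power envelope, and extracts
    per-breath sound energy, sound intensity, respiratory rate and acoustic
    ventilation. The ventilatory anaerobic threshold is detected as the
    breakpoint of a two-segment piecewise-linear fit to an acoustic feature
    trace and compared against the ventilatory-equivalents (VE/VO2 nadir)
    reference; oxygen uptake is regressed from the acoustic features with
    random-forest and linear backends under subject-specific and
    leave-one-subject-out validation. A synthetic CPET generator with known
    ground truth (threshold time, peak oxygen uptake, breathing-rate
    trajectory) makes the whole pipeline testable end to end, and agreement
    statistics (Bland-Altman, Pearson, cohort summaries) match standard
    method-comparison practice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
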