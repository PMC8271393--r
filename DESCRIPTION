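Package: mealbci
Title: Hybrid Brain-Computer-Interface Meal-Assist Controller
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing toolkit for a hybrid scalp-EEG controller of a
    meal-assist robot: triple eye-blink activation detection from the
    prefrontal channel, steady-state visual evoked potential (SSVEP) food
    selection from occipital channels via the multivariate synchronization
    index, chewing detection from temporal-channel EMG, the meal-cycle
    state machine, and evaluation metrics (accuracy, Wolpaw information
    transfer rate, false-positive rate). Includes elliptic IIR filtering,
    EDF/BDF/CSV recording I/O and a synthetic session generator with
    ground-truth event logs, so the whole pipeline is testable without
    subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
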