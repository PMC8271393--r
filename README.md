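# mealbci

Signal processing for a hybrid brain–computer-interface meal-assist robot
controller, for researchers and engineers building assistive BCI systems
from scalp electrodes alone. A meal cycle needs three decisions, each read
from a different electrode site with training-free algorithms:

- **activation** — a deliberate triple eye-blink at prefrontal FPz: three
  supra-threshold peaks with both inter-peak intervals strictly inside
  (0.3, 0.8) s, with a Ricker-wavelet rescue pass for borderline peaks;
- **food selection** — the steady-state visual evoked potential (SSVEP) at
  occipital O1/Oz/O2 (re-referenced to Cz) while the user gazes at one of
  five LEDs flickering at 7.4, 8.43, 9.8, 11.7, 13.7 Hz, decoded by a
  multivariate synchronization index: for stacked epoch X and sine/cosine
  references Y, whiten the auto-blocks of the joint correlation matrix and
  score the eigenvalue entropy

  S = 1 + Σᵢ λ′ᵢ log λ′ᵢ / log P,  λ′ᵢ = λᵢ/Σλ,

  choosing the stimulus frequency with the largest S;
- **meal confirmation** — chewing EMG at temporal T7/T8 via the envelope
  MA(|diff(MA(|x|))|), detected when the envelope exceeds half the median
  calibration value for strictly more than 2 s of samples (1024 at
  512 Hz), confirmed online by three consecutive windows.

A finite-state machine turns detections into robot commands (LED_ON,
GRAB_FOOD, FEED, RETURN_SPOON) with a blink lockout during meals and a
10-s chew timeout. Performance is scored by per-modality accuracy, the
Wolpaw information transfer rate

ITR = (60/T)·[log₂N + P·log₂P + (1−P)·log₂((1−P)/(N−1))] bit/min,

and the false-positive rate over the session. Elliptic IIR filtering
(designed in-package from the analog prototype up, since no R filter-design
library is available), EDF/BDF/CSV recording I/O, and a seeded synthetic
session generator with ground-truth event logs round out the toolkit.

## Worked example

```r
library(mealbci)
set.seed(1)
proto <- session_protocol(n_trials = 2)            # 10 cycles
prm <- synthesis_params(fs = 512, ssvep_snr = 2, seed = 1)
sess <- synth_session(proto, prm)
sess$recording
#> <bci_recording> 7 channels x 117760 samples (230.00 s at 512 Hz)
#>   channels: FPz, T7, T8, O1, Oz, O2, Cz

# decode the first gaze window: 2-54 Hz bandpass, Cz re-reference, 4-s epoch
occ <- c("O1", "Oz", "O2")
filt <- rereference(apply_filter(sess$recording, make_filter("ssvep", 512)), occ, "Cz")
gaze <- sess$events[sess$events$label == "gaze", ]
classify_ssvep(epoch_at(filt, gaze$onset_s[1], 4, occ))
#> <class_decision> stimulus 0 (7.4 Hz); S = 0.010, 0.002, 0.002, 0.001, 0.002
gaze$value[1]                                      # cued index
#> [1] 0

# score the whole session
pred <- vapply(seq_len(nrow(gaze)), function(i)
  classify_ssvep(epoch_at(filt, gaze$onset_s[i], 4, occ))$chosen_index, 0L)
acc <- detection_accuracy(pred, sess$events, "ssvep")
sprintf("SSVEP accuracy: %.2f %% -> ITR %.2f bit/min", acc, itr_wolpaw(acc/100, 5, 4))
#> [1] "SSVEP accuracy: 90.00 % -> ITR 24.79 bit/min"
```

The synchronization index of the cued 7.4-Hz stimulus (0.010) dominates
the other four candidates, so cycle 1 is decoded correctly; 9 of the 10
cycles decode correctly at this signal-to-background ratio, worth
24.79 bit/min at the 4-s selection time. `run_session()` replays a
recording through the causal 0.5–55 Hz online path and emits the command
log; `inst/cli/mealbci.R` exposes `simulate`, `detect-eb`, `detect-emg`,
`classify-ssvep`, `evaluate` and `run-session` as shell subcommands.

Bundled under `inst/extdata/` are the published five-subject reference
tables (per-subject SSVEP accuracies/ITRs by channel-count and epoch
condition, and blink/chew false-positive rates), used by the metrics
cross-checks: `itr_wolpaw(accuracy/100, 5, epoch)` reproduces every
printed ITR cell to ±0.01 bit/min, and the row means reproduce the
printed 0.11/0.08 times-per-minute averages.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch against the installed package:
synthesizes the six-trial (30-cycle) session protocol at the given seed,
runs all three detectors with auto-calibrated thresholds, prints the
per-modality accuracies, the session ITR and the reference-table
cross-checks, and writes the JSON report to `--out`.
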