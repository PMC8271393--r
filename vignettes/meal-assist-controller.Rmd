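---
title: "Methods: the hybrid scalp-signal meal-assist controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid scalp-signal meal-assist controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the signals

A meal-assist robot needs three decisions from its user, all readable from
scalp electrodes without any training session:

1. **"Start a cycle"** — a deliberate triple eye-blink, visible as three
   large positive deflections at the prefrontal electrode FPz.
2. **"This food"** — the user gazes at one of five LEDs flickering at
   7.4, 8.43, 9.8, 11.7 and 13.7 Hz; the occipital EEG (O1, Oz, O2)
   phase-locks to the attended flicker (the steady-state visual evoked
   potential, SSVEP).
3. **"I am eating"** — chewing produces broadband electromyographic (EMG)
   activity at the temporal electrodes T7 and T8; its presence closes the
   cycle, its absence for 10 s returns the spoon.

`mealbci` implements the detectors, the decoder, the cycle state machine,
the evaluation metrics, and a synthetic-session generator so that every
stage is testable without subject recordings.

# Preprocessing

All paths use elliptic IIR filters (implemented in-package down to the
Jacobi-elliptic analog prototype, because the installed R stack has no
filter-design library): blink path 0.5–5 Hz, SSVEP path 2–54 Hz (the local
mains frequency is 60 Hz), EMG path 0.5 Hz highpass, and a single shared
0.5–55 Hz bandpass for the 128-Hz online mode. Filters are realised as
second-order sections; the transfer-function form of an order-4 bandpass
with a 0.5-Hz edge at 512 Hz would be numerically fragile.

Unstated parameters were fixed once: prototype order 4, 0.5 dB passband
ripple, 40 dB stopband attenuation — standard EEG practice, stable at both
128 and 512 Hz. Two consequences are documented rather than hidden:

* An elliptic bandpass has no DC *null*; a constant input leaks through at
  the −40 dB stopband floor (≤ 1 %), which is what "DC removed" means here.
* 60 Hz lies in the order-4 transition band of the 2–54 Hz filter
  (≈ −6 dB). Full 40-dB suppression of 60 Hz requires `order = 8`, which
  `make_filter()` accepts; the default stays at the conventional order 4.
  The SSVEP decoder is unaffected, since it projects onto references far
  below 54 Hz.

Offline filtering defaults to zero-phase (forward–backward, so the
magnitude response applies twice and peak latencies are preserved); the
online path is causal. Whether the original offline analysis was causal or
zero-phase is unknowable from the source; both modes are explicit
arguments. Zero-phase edge transients are suppressed by odd extension plus
per-section steady-state initial conditions, with ~1 s of padding because
the 0.5-Hz band edge rings for hundreds of samples.

# Triple-blink detection

Peaks above a subject threshold are screened: exactly three supra-threshold
peaks, and both inter-peak intervals strictly inside (0.3, 0.8) s. The
threshold is half the mean amplitude of blinks detected in a calibration
pass. "Exactly three" is enforced — a fourth supra-threshold peak voids
the decision — because the screen asks whether the number of qualifying
peaks *is* three, and because it is the conservative reading for an
activation switch.

If the direct pass finds no qualifying triple, a continuous-wavelet rescue
runs: a Ricker (Mexican-hat) filter bank spanning 100–400 ms blink widths,
scale-averaged. Two implementation choices matter:

* **Amplitude normalisation.** The trace is normalised so a blink-width
  pulse of amplitude A produces a trace peak ≈ A; the amplitude threshold
  then keeps its physical meaning on the rescue pass. Because the Ricker
  kernels are zero-mean, the rescue trace also cancels the slow baseline
  undershoot that the 0.5-Hz bandpass edge prints after each blink — this
  undershoot depresses the *third* peak of a triple and is precisely the
  failure mode the rescue recovers.
* **Timing snap-back.** Overlapping filter-bank responses can bias a peak
  location by a sample; peak times are snapped to the local maximum of the
  input trace within ±50 ms, so the strict interval screen is judged on
  signal timing, not on filter-bank artefacts.

One caveat the tests respect: amplitude monotonicity (detected at t ⇒
detected at every t′ < t) holds only while the set of supra-threshold
peaks is the three blinks; lowering the threshold far enough to admit a
fourth background peak voids detection *by design* of the exact-count
rule. The property is tested over the threshold range where the peak set
is stable.

# SSVEP decoding by synchronization index

For a candidate stimulus frequency, references are sine/cosine pairs at
harmonics h = 1..H (default H = 2; the third harmonic of 13.7 Hz would
leave the 54-Hz passband). The index stacks the N-channel epoch X and the
2H reference rows Y, forms the joint correlation matrix

$$C = \frac{1}{M} Z Z^\top,\quad Z = \begin{bmatrix} X \\ Y\end{bmatrix},$$

whitens the two auto-blocks to identity, takes eigenvalues
$\lambda_i$ of the whitened joint matrix, normalises
$\lambda_i' = \lambda_i / \sum\lambda$, and returns the entropy-based
index

$$S = 1 + \frac{\sum_i \lambda_i' \log \lambda_i'}{\log P},$$

with P the joint dimension. Independence gives a flat spectrum and S ≈ 0;
phase-locking concentrates it and raises S. The attended stimulus is the
argmax over the five candidate frequencies; ties break to the lowest
index, deterministically. No per-subject training is involved.

Design choices:

* **Correlation, not covariance** — rows are centred and
  variance-normalised, making S exactly invariant to per-channel gain.
* **Degenerate blocks.** A rank-deficient auto-block (constant channel, or
  noiseless sinusoids spanning fewer dimensions than channels) is handled
  by *truncating* the whitening to the non-degenerate subspace, with a
  warning. Flooring tiny eigenvalues instead would amplify rounding noise
  by 1/√tol and destroy machine-precision scale invariance.
* **The "extended" variant.** The cited estimator family has a plain and
  an extended form; the source names the extension without internals. Here
  `estimator = "emsi"` (the default) augments the EEG block with
  one-sample time-delayed copies before stacking, capturing a stimulus–
  response phase lag that the plain correlation of `"msi"` cannot; both
  variants sit behind one interface so their difference is testable. This
  reading is a documented package choice, not a reproduction of
  unpublished code.

# Chewing detection

The envelope is MA(|diff(MA(|x|))|): rectify, 250-ms moving average,
first difference (scaled by fs), rectify, smooth again. Chewing is
declared when the envelope exceeds the subject threshold — half the
*median* of a calibration envelope that contains chewing — for strictly
more than 2 s of samples (1024 at 512 Hz; a count of exactly 1024 is not
a detection). The per-sample maximum of the T7 and T8 envelopes is
thresholded, keeping the rule symmetric in the two channels.

The median-based threshold only makes sense calibrated *on chewing*: the
median of a mostly-idle recording sits at the noise floor, and half of it
would flag everything. Where no instructed calibration exists (the
self-contained session replay), the loudest 5-s span of the envelope
stands in for it; this stand-in is a package choice, documented here.

The online criterion is stricter: the 2-s rule must fire in three
consecutive 1-s-slide windows before the cycle closes (a spoon descending
on a false EMG is the costlier error); `consecutive = FALSE` relaxes this
to any three.

# The meal-cycle state machine

IDLE → (triple blink) → STIMULATING (LED on) → (first classification after
≥ 4 s of stimulation) → SELECTING (LED off, grab) → FEEDING → CHEW_MONITOR
→ either triple-confirmed chewing or a 10-s timeout → RETURNING → IDLE.
Blink events outside IDLE and classifications outside STIMULATING are
discarded — the lockout is what keeps the false-positive rate of an
always-on system tolerable. Robot actions are simulated as timed log
events (grab 2 s, feed 2 s, return 2 s, configurable); hardware is out of
scope. The commit rule — classify each new 4-s window and commit the first
decision at least 4 s after stimulation onset — is the package's choice
for the online path, where the source describes only the offline epoching.

Replay is deterministic: the same recording and configuration produce an
identical event log, and every command is preceded in the log by the
detection that licensed it.

# Metrics

Accuracy is per-cycle per cent correct. The information transfer rate is
Wolpaw's
$$\mathrm{ITR} = \frac{60}{T}\Big[\log_2 N + P\log_2 P + (1-P)\log_2\frac{1-P}{N-1}\Big]$$
bits/min with N = 5 and T equal to the *epoch length* (3 or 4 s) — this
identification of T is verified by the fact that it reproduces all twenty
published per-subject ITR cells to ±0.01 bit/min, which would fail for any
T including the gaze or rest time. Note the bracket is a symmetric-channel
mutual information: it is zero exactly at chance (P = 1/N) and positive
on *both* sides; values are returned unclamped. The false-positive rate is
detections outside allowed windows per minute of the whole session, and
group averages are arithmetic means per field — the mean of per-subject
ITRs, not the ITR of the mean accuracy (the formula is nonlinear in P).
Report tables round half-up at two decimals. One documented discrepancy in
the published numbers themselves: the per-subject false-positive rows
average to 0.08/min for chewing, while the running text prints 0.09; the
package reproduces 0.08 from the rows and leaves the discrepancy alone.

# The synthetic world

`synth_session()` renders the evaluation protocol: per cycle, 3 s
instruction, 3 s blink window (triple centred, 0.5-s spacing), 3 s food
cue, 5 s gaze (the cued stimulus as an occipital sinusoid with random
phase), 3 s chew cue, 5 s chew window (a centred broadband 15–60 Hz burst
covering 90 % of it), with 10-s rests between 5-cycle trials and each
stimulus cued once per trial in random order. Defaults are the stated
conditions where stated (6 trials, 30 cycles, 22 s per cycle) and
field-realistic choices where not: 100 µV blinks of 200 ms width over a
10 µV RMS 1/f background, 40 µV RMS chew bursts, SSVEP amplitude set so
narrowband power over in-band background power equals `ssvep_snr`.

The timeline question the source leaves open — segment durations sum to
≈ 11.8 min including rests while the scored "entire experimental period"
is 10.5 min — is left open here too: durations are configurable and the
generator forces no agreement.

What the generator does *not* emulate: volume conduction (channels carry
independent noise), eye movements other than blinks, harmonic-rich or
subject-variable SSVEP spectra (fundamental only by default), food-
dependent EMG morphology. A green test on this world therefore
establishes algorithmic correctness — thresholds, counts, windows, state
transitions, spectral selectivity — not field performance on human EEG:
the published accuracies (94.67/83.33/97.33 %) live on the subjects'
recordings, which are an external resource.

# Numerical notes

* Elliptic prototypes use Landen/AGM recursions; designs agree with an
  independent reference implementation to ~1e-10 across all four modality
  filters (frozen response values are asserted in the test suite).
* Second-order-section pairing groups conjugate pairs, nearest zeros to
  poles closest to the unit circle; any valid pairing gives the same
  response in double precision, and each section is verified stable.
* Peak suppression uses strictly-closer-than-0.3-s, so two peaks at
  exactly 0.3 s both survive and the strict interval screen (not the
  suppressor) rejects them; interval screens are strict inequalities, and
  tests compare against sample-quantised ground truth.
* Event times are seconds from recording start; windows are half-open
  [start, start + len); window timestamps are window *end* times (causal).
* All generators are bit-reproducible per seed.

# Limitations

Single-subject thresholds are inputs, not adaptive; no artifact-subspace
removal or emergency-stop channel (out of scope); EDF support covers the
common 16-bit layout (one data record) and BDF is read-only; the "emsi"
delay embedding is a documented interpretation of a cited but unspecified
extension.
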