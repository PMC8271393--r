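# Synthetic scalp recordings with ground truth.
#
# Emulates the signals each detector consumes: smooth positive blink
# deflections at FPz, narrowband occipital oscillations at the flicker
# frequencies over 1/f background, and broadband high-amplitude chewing
# bursts at T7/T8, laid out on the session protocol timeline. The output is
# a stated world for testing the pipeline, not forward-modelled EEG.

#' Session protocol description
#'
#' One cycle shows an instruction screen, a 3-s blink window, a food cue, a
#' 5-s gaze (flicker) window, a chew cue and a 5-s chew window; five cycles
#' (one per stimulus, in random order) make a trial, trials are separated
#' by a rest. The defaults are the evaluation protocol: 6 trials of 5
#' cycles (30 cycles), 22 s per cycle plus 10-s rests.
#'
#' @param n_trials number of trials (default 6).
#' @param cycles_per_trial cycles per trial (default 5, one per stimulus).
#' @param instruction_s,eb_window_s,food_cue_s,gaze_s,chew_cue_s,chew_s,rest_s
#'   segment durations in seconds (defaults 3, 3, 3, 5, 3, 5, 10).
#' @param stimulus_order optional integer matrix (\code{n_trials} x
#'   \code{cycles_per_trial}, 0-based stimulus indices); each row must be a
#'   permutation of \code{0:(cycles_per_trial-1)}. Randomised per trial if
#'   omitted (uses the current RNG state).
#' @return a \code{session_protocol} object.
#' @examples
#' p <- session_protocol(n_trials = 1)
#' cycle_duration_s(p)  # 22
#' @export
session_protocol <- function(n_trials = 6, cycles_per_trial = 5,
                             instruction_s = 3, eb_window_s = 3, food_cue_s = 3,
                             gaze_s = 5, chew_cue_s = 3, chew_s = 5, rest_s = 10,
                             stimulus_order = NULL) {
  durs <- c(instruction_s, eb_window_s, food_cue_s, gaze_s, chew_cue_s, chew_s, rest_s)
  if (any(durs <= 0)) stop("all protocol durations must be positive")
  if (n_trials < 1 || cycles_per_trial < 1) stop("need at least one trial and one cycle")
  if (is.null(stimulus_order)) {
    stimulus_order <- t(vapply(seq_len(n_trials),
                               function(i) sample.int(cycles_per_trial) - 1L,
                               integer(cycles_per_trial)))
    if (cycles_per_trial == 1) stimulus_order <- matrix(0L, n_trials, 1)
  }
  stimulus_order <- matrix(as.integer(stimulus_order), n_trials, cycles_per_trial)
  ok <- apply(stimulus_order, 1, function(r) setequal(r, 0:(cycles_per_trial - 1)))
  if (!all(ok)) stop("each trial's stimulus_order must be a permutation of 0:",
                     cycles_per_trial - 1)
  structure(list(n_trials = n_trials, cycles_per_trial = cycles_per_trial,
                 instruction_s = instruction_s, eb_window_s = eb_window_s,
                 food_cue_s = food_cue_s, gaze_s = gaze_s, chew_cue_s = chew_cue_s,
                 chew_s = chew_s, rest_s = rest_s, stimulus_order = stimulus_order),
            class = "session_protocol")
}

#' @rdname session_protocol
#' @param protocol a \code{session_protocol}.
#' @export
cycle_duration_s <- function(protocol) {
  with(protocol, instruction_s + eb_window_s + food_cue_s + gaze_s + chew_cue_s + chew_s)
}

#' Synthesis parameters
#'
#' Amplitudes follow typical scalp-recorded magnitudes: ~100 uV voluntary
#' blinks at FPz over a ~10 uV RMS EEG background, chewing bursts well
#' above background at the temporal sites. \code{ssvep_snr} is the ratio of
#' narrowband stimulus power to background power within the stimulus band
#' (+/- 0.5 Hz); \code{Inf} means no background on the occipital channels.
#'
#' @param fs sampling rate, Hz (512 offline, 128 online).
#' @param blink_amplitude_uv blink peak amplitude, microvolts.
#' @param blink_width_s blink pulse width (raised cosine), seconds.
#' @param ssvep_snr narrowband/background power ratio in the stimulus band.
#' @param n_harmonics_emitted harmonics added to the SSVEP (default 1 =
#'   fundamental only, keeping the classifier's harmonic handling an
#'   independent choice).
#' @param emg_burst_band broadband chew-burst band, Hz.
#' @param emg_burst_rms_uv RMS amplitude of chew bursts, microvolts.
#' @param noise_rms_uv background RMS, microvolts.
#' @param noise_spectrum \code{"one_over_f"} (EEG-like, default) or
#'   \code{"white"}.
#' @param seed integer; fully determines the output.
#' @return a \code{synthesis_params} object.
#' @export
synthesis_params <- function(fs = 512, blink_amplitude_uv = 100, blink_width_s = 0.2,
                             ssvep_snr = 1, n_harmonics_emitted = 1,
                             emg_burst_band = c(15, 60), emg_burst_rms_uv = 40,
                             noise_rms_uv = 10,
                             noise_spectrum = c("one_over_f", "white"),
                             seed = 1L) {
  noise_spectrum <- match.arg(noise_spectrum)
  if (fs <= 0) stop("fs must be positive")
  if (blink_width_s <= 0) stop("blink_width_s must be positive")
  if (ssvep_snr < 0) stop("ssvep_snr must be >= 0")
  structure(list(fs = fs, blink_amplitude_uv = blink_amplitude_uv,
                 blink_width_s = blink_width_s, ssvep_snr = ssvep_snr,
                 n_harmonics_emitted = n_harmonics_emitted,
                 emg_burst_band = emg_burst_band,
                 emg_burst_rms_uv = emg_burst_rms_uv,
                 noise_rms_uv = noise_rms_uv, noise_spectrum = noise_spectrum,
                 seed = as.integer(seed)),
            class = "synthesis_params")
}

#' The five flicker stimulus frequencies
#'
#' @param freqs_hz stimulus frequencies, Hz (defaults 7.4, 8.43, 9.8, 11.7,
#'   13.7 -- one per food target: rice plus four side dishes).
#' @param target_labels food label per stimulus index.
#' @return a \code{stimulus_set} object.
#' @export
stimulus_set <- function(freqs_hz = c(7.4, 8.43, 9.8, 11.7, 13.7),
                         target_labels = c("rice", "side1", "side2", "side3", "side4")) {
  if (anyDuplicated(freqs_hz) || any(freqs_hz <= 0)) {
    stop("stimulus frequencies must be distinct and positive")
  }
  if (length(target_labels) != length(freqs_hz)) stop("one label per frequency required")
  structure(list(freqs_hz = freqs_hz, target_labels = target_labels),
            class = "stimulus_set")
}

# background noise of length n, RMS scaled; 1/f amplitude shaping via FFT
.synth_noise <- function(n, params) {
  if (params$noise_rms_uv == 0) return(numeric(n))
  x <- stats::rnorm(n)
  if (params$noise_spectrum == "one_over_f") {
    X <- stats::fft(x)
    f <- c(0, seq_len(n - 1))
    f <- pmin(f, n - f)                    # two-sided frequency index
    shape <- c(0, 1 / sqrt(f[-1]))         # amplitude ~ f^(-1/2) => power ~ 1/f
    x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  }
  x * params$noise_rms_uv / stats::sd(x)
}

# raised-cosine pulse sampled on the signal grid, peak at center_s
.blink_pulse <- function(n, fs, center_s, amp, width_s) {
  t <- (seq_len(n) - 1) / fs
  u <- (t - center_s) / width_s
  ifelse(abs(u) < 0.5, amp * 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Synthesise a train of eye blinks on one channel
#'
#' @param n_blinks number of blinks (>= 0).
#' @param interval_s spacing between successive blink peaks, seconds.
#' @param params a \code{synthesis_params}.
#' @param duration_s signal length, seconds.
#' @param start_s time of the first blink peak (default centres the train).
#' @return list with \code{signal} (numeric vector, microvolts) and
#'   \code{peak_times_s} (ground truth).
#' @examples
#' b <- synth_blink_train(3, 0.5, synthesis_params(seed = 7), 4)
#' diff(b$peak_times_s)
#' @export
synth_blink_train <- function(n_blinks, interval_s, params, duration_s,
                              start_s = NULL) {
  if (n_blinks < 0) stop("n_blinks must be >= 0")
  if (n_blinks > 1 && interval_s < params$blink_width_s) {
    stop("interval_s = ", interval_s, " s is smaller than the blink width (",
         params$blink_width_s, " s); blinks would fuse")
  }
  span <- if (n_blinks > 1) (n_blinks - 1) * interval_s else 0
  if (span + params$blink_width_s > duration_s) {
    stop("blink train (", span, " s) does not fit in ", duration_s, " s")
  }
  if (is.null(start_s)) start_s <- (duration_s - span) / 2
  n <- round(duration_s * params$fs)
  set.seed(params$seed)
  x <- .synth_noise(n, params)
  peaks <- if (n_blinks > 0) start_s + (seq_len(n_blinks) - 1) * interval_s else numeric(0)
  for (pt in peaks) {
    x <- x + .blink_pulse(n, params$fs, pt, params$blink_amplitude_uv, params$blink_width_s)
  }
  list(signal = x, peak_times_s = peaks)
}

# in-band background power (uV^2) within +/- half_bw of freq, via periodogram
.band_power <- function(x, fs, freq, half_bw = 0.5) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f > 0 & f <= fs / 2 & abs(f - freq) <= half_bw
  if (!any(sel)) return(0)
  sum(Mod(X[sel])^2) * 2 / n^2
}

#' Synthesise a multichannel SSVEP response
#'
#' Each channel carries a sinusoid at \code{freq} (plus
#' \code{params$n_harmonics_emitted - 1} harmonics at half the fundamental
#' amplitude each) with a random common phase, embedded in background noise
#' so that narrowband power over in-band background power equals
#' \code{params$ssvep_snr}.
#'
#' @param freq stimulus frequency, Hz (must be below fs/2).
#' @param params a \code{synthesis_params}.
#' @param duration_s epoch length, seconds (>= 1).
#' @param n_channels number of channels.
#' @return channels-by-time numeric matrix, microvolts.
#' @export
synth_ssvep <- function(freq, params, duration_s, n_channels = 3) {
  if (freq <= 0) stop("freq must be positive")
  if (freq >= params$fs / 2) {
    stop("freq = ", freq, " Hz violates the sampling theorem at fs = ", params$fs)
  }
  if (duration_s < 1) stop("duration_s must be >= 1 s")
  n <- round(duration_s * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  set.seed(params$seed)
  phase <- stats::runif(1, 0, 2 * pi)
  noise <- t(vapply(seq_len(n_channels), function(i) .synth_noise(n, params),
                    numeric(n)))
  if (params$ssvep_snr == 0) return(noise)
  # amplitude from the SNR definition: A^2/2 = snr * in-band background power
  pbg <- mean(vapply(seq_len(n_channels), function(i)
    .band_power(noise[i, ], params$fs, freq), 0))
  amp <- if (is.infinite(params$ssvep_snr) || pbg == 0) 1 else sqrt(2 * params$ssvep_snr * pbg)
  sig <- amp * sin(2 * pi * freq * t + phase)
  H <- max(1, params$n_harmonics_emitted)
  if (H > 1) {
    for (h in 2:H) {
      if (h * freq < params$fs / 2) {
        sig <- sig + (amp / 2) * sin(2 * pi * h * freq * t + h * phase)
      }
    }
  }
  if (is.infinite(params$ssvep_snr)) {
    matrix(rep(sig, n_channels), nrow = n_channels, byrow = TRUE)
  } else {
    sweep(noise, 2, sig, "+")
  }
}

#' Synthesise chewing-burst EMG on one channel
#'
#' Broadband high-amplitude activity inside the burst windows, baseline
#' background elsewhere.
#'
#' @param duration_s signal length, seconds.
#' @param burst_windows list of \code{c(start, stop)} pairs in seconds;
#'   must lie within the signal and not overlap.
#' @param params a \code{synthesis_params}.
#' @return numeric vector, microvolts.
#' @export
synth_chew_burst <- function(duration_s, burst_windows, params) {
  if (length(burst_windows) > 0) {
    w <- do.call(rbind, burst_windows)
    if (any(w[, 1] >= w[, 2])) stop("burst windows must have start < stop")
    if (any(w < 0) || any(w > duration_s)) stop("burst windows must lie within the signal")
    o <- order(w[, 1])
    if (nrow(w) > 1 && any(w[o, 1][-1] < w[o, 2][-nrow(w)])) {
      stop("burst windows overlap")
    }
  }
  n <- round(duration_s * params$fs)
  set.seed(params$seed)
  x <- .synth_noise(n, params)
  if (length(burst_windows) == 0) return(x)
  t <- (seq_len(n) - 1) / params$fs
  lo <- params$emg_burst_band[1]
  hi <- min(params$emg_burst_band[2], 0.45 * params$fs)
  for (bw in burst_windows) {
    sel <- t >= bw[1] & t < bw[2]
    m <- sum(sel)
    if (m < 4) next
    b <- stats::rnorm(m)
    B <- stats::fft(b)
    f <- (seq_len(m) - 1) * params$fs / m
    f2 <- pmin(f, params$fs - f)
    keep <- f2 >= lo & f2 <= hi
    b <- Re(stats::fft(B * keep, inverse = TRUE)) / m
    x[sel] <- x[sel] + b * params$emg_burst_rms_uv / stats::sd(b)
  }
  x
}

#' Synthesise a full session with ground truth
#'
#' Lays the protocol on a timeline and renders all seven channels (FPz, T7,
#' T8, O1, Oz, O2, Cz): a triple blink centred in each blink window, the
#' cued stimulus oscillation on the occipital channels during each gaze
#' window, and a chew burst covering most of each chew window. All
#' channels carry independent background noise.
#'
#' @param protocol a \code{session_protocol}.
#' @param params a \code{synthesis_params}; \code{params$seed} fully
#'   determines recording and events.
#' @param stimuli a \code{stimulus_set}.
#' @param blink_interval_s spacing inside the blink triple (default 0.5 s).
#' @param chew_fill fraction of the chew window carrying the burst
#'   (default 0.9, centred).
#' @return list with \code{recording} (a \code{bci_recording}),
#'   \code{events} (ground-truth \code{event_log}: \code{eb} spans from
#'   first to last blink peak, \code{gaze} spans with stimulus index as
#'   value, \code{chew} burst spans) and \code{protocol}.
#' @examples
#' s <- synth_session(session_protocol(n_trials = 1),
#'                    synthesis_params(fs = 128, seed = 3))
#' s$recording
#' @export
synth_session <- function(protocol, params, stimuli = stimulus_set(),
                          blink_interval_s = 0.5, chew_fill = 0.9) {
  stopifnot(inherits(protocol, "session_protocol"),
            inherits(params, "synthesis_params"))
  if (max(stimuli$freqs_hz) >= params$fs / 2) {
    stop("stimulus frequencies must lie below fs/2")
  }
  set.seed(params$seed)
  fs <- params$fs
  labels <- c("FPz", "T7", "T8", "O1", "Oz", "O2", "Cz")
  cyc <- cycle_duration_s(protocol)
  total_s <- protocol$n_trials * protocol$cycles_per_trial * cyc +
    (protocol$n_trials - 1) * protocol$rest_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  X <- t(vapply(labels, function(l) .synth_noise(n, params), numeric(n)))
  rownames(X) <- labels

  ev_on <- numeric(0); ev_dur <- numeric(0); ev_lab <- character(0); ev_val <- numeric(0)
  occ <- c("O1", "Oz", "O2")
  for (tr in seq_len(protocol$n_trials)) {
    trial_t0 <- (tr - 1) * (protocol$cycles_per_trial * cyc + protocol$rest_s)
    for (cy in seq_len(protocol$cycles_per_trial)) {
      t0 <- trial_t0 + (cy - 1) * cyc
      # blink triple centred in the blink window
      eb0 <- t0 + protocol$instruction_s
      span <- 2 * blink_interval_s
      p1 <- eb0 + (protocol$eb_window_s - span) / 2
      pk <- p1 + (0:2) * blink_interval_s
      for (pt in pk) {
        X["FPz", ] <- X["FPz", ] + .blink_pulse(n, fs, pt, params$blink_amplitude_uv,
                                                params$blink_width_s)
      }
      ev_on <- c(ev_on, pk[1]); ev_dur <- c(ev_dur, span)
      ev_lab <- c(ev_lab, "eb"); ev_val <- c(ev_val, NA_real_)
      # gaze window: cued stimulus on occipital channels
      g0 <- eb0 + protocol$eb_window_s + protocol$food_cue_s
      idx <- protocol$stimulus_order[tr, cy]
      freq <- stimuli$freqs_hz[idx + 1]
      sel <- t >= g0 & t < g0 + protocol$gaze_s
      m <- sum(sel)
      phase <- stats::runif(1, 0, 2 * pi)
      pbg <- mean(vapply(occ, function(ch) .band_power(X[ch, sel], fs, freq), 0))
      amp <- if (is.infinite(params$ssvep_snr) || pbg <= 1e-12) 10 else
        sqrt(2 * params$ssvep_snr * pbg)
      tt <- t[sel]
      sig <- amp * sin(2 * pi * freq * tt + phase)
      H <- max(1, params$n_harmonics_emitted)
      if (H > 1) for (h in 2:H) {
        if (h * freq < fs / 2) sig <- sig + (amp / 2) * sin(2 * pi * h * freq * tt + h * phase)
      }
      taper <- .tukey_taper(m, fs, 0.1)
      for (ch in occ) X[ch, sel] <- X[ch, sel] + sig * taper
      ev_on <- c(ev_on, g0); ev_dur <- c(ev_dur, protocol$gaze_s)
      ev_lab <- c(ev_lab, "gaze"); ev_val <- c(ev_val, idx)
      # chew window: centred burst covering chew_fill of it
      c0 <- g0 + protocol$gaze_s + protocol$chew_cue_s
      blen <- chew_fill * protocol$chew_s
      b0 <- c0 + (protocol$chew_s - blen) / 2
      selb <- t >= b0 & t < b0 + blen
      mb <- sum(selb)
      lo <- params$emg_burst_band[1]; hi <- min(params$emg_burst_band[2], 0.45 * fs)
      for (ch in c("T7", "T8")) {
        b <- stats::rnorm(mb)
        B <- stats::fft(b)
        f <- (seq_len(mb) - 1) * fs / mb
        f2 <- pmin(f, fs - f)
        b <- Re(stats::fft(B * (f2 >= lo & f2 <= hi), inverse = TRUE)) / mb
        X[ch, selb] <- X[ch, selb] + b * params$emg_burst_rms_uv / stats::sd(b)
      }
      ev_on <- c(ev_on, b0); ev_dur <- c(ev_dur, blen)
      ev_lab <- c(ev_lab, "chew"); ev_val <- c(ev_val, NA_real_)
    }
  }
  list(recording = recording(X, fs, labels),
       events = event_log(ev_on, ev_dur, ev_lab, ev_val),
       protocol = protocol)
}

# short cosine taper at segment edges to avoid onset clicks
.tukey_taper <- function(n, fs, ramp_s) {
  r <- min(round(ramp_s * fs), floor(n / 2))
  w <- rep(1, n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(r)) / r))
    w[seq_len(r)] <- ramp
    w[(n - r + 1):n] <- rev(ramp)
  }
  w
}
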