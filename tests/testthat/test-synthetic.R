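# Generator contracts: construction, determinism, ground-truth consistency
# and the spectral SNR property.

test_that("blink trains carry the requested peaks over background", {
  p <- synthesis_params(seed = 7)
  b <- synth_blink_train(3, 0.5, p, 4)
  expect_length(b$peak_times_s, 3)
  expect_equal(diff(b$peak_times_s), c(0.5, 0.5))
  i <- round(b$peak_times_s * p$fs) + 1
  expect_true(all(b$signal[i] > 80))       # ~100 uV peaks over 10 uV noise
  empty <- synth_blink_train(0, 0.5, p, 4)
  expect_length(empty$peak_times_s, 0)
  expect_lt(max(abs(empty$signal)), 80)
  again <- synth_blink_train(3, 0.5, p, 4)
  expect_identical(b$signal, again$signal)  # bit-reproducible per seed
  expect_error(synth_blink_train(3, 0.05, p, 4), "width")
  expect_error(synth_blink_train(9, 0.5, p, 4), "fit")
})

test_that("ssvep epochs have a spectral peak at the stimulus, monotone in SNR", {
  peak_ratio <- function(snr, freq = 9.8, seed = 11) {
    p <- synthesis_params(ssvep_snr = snr, seed = seed)
    ep <- synth_ssvep(freq, p, 4, 3)
    n <- ncol(ep)
    f <- (0:(n - 1)) * p$fs / n
    spec <- Mod(stats::fft(ep[1, ]))^2
    at <- function(fr) max(spec[abs(f - fr) < 0.3])
    at(freq) / mean(c(at(freq - 2), at(freq + 2)))
  }
  r <- vapply(c(0, 0.5, 2, 8), peak_ratio, 0)
  expect_lt(r[1], 5)                        # no stimulus-locked component
  expect_true(all(diff(r[-1]) > 0))         # margin grows with SNR
  expect_gt(r[4], 10)
  # noiseless limit: energy only at the stimulus bin
  p <- synthesis_params(ssvep_snr = Inf, seed = 1)
  ep <- synth_ssvep(9.8, p, 4, 3)
  n <- ncol(ep)
  f <- (0:(n - 1)) * p$fs / n
  spec <- Mod(stats::fft(ep[2, ]))^2
  expect_gt(sum(spec[abs(f - 9.8) < 0.3]) / sum(spec[f > 0 & f < p$fs / 2]), 0.49)
  expect_error(synth_ssvep(300, p, 4), "sampling theorem")
})

test_that("chew bursts drive the detector per the 2-s rule", {
  fs <- 512
  p <- synthesis_params(fs = fs, seed = 21)
  hp <- make_filter("emg", fs)
  run <- function(burst) {
    x <- synth_chew_burst(8, burst, p)
    env <- emg_envelope(apply_filter(x, hp), fs)
    base <- synth_chew_burst(8, list(), p)
    benv <- emg_envelope(apply_filter(base, hp), fs)
    thr <- calibrate_emg_threshold(env[round(2.5 * fs):round(5 * fs)])
    list(env = env, benv = benv, thr = thr,
         det = detect_chewing(env, fs, thr)$detected)
  }
  long <- run(list(c(2.5, 5.0)))            # 2.5-s burst: above the 2-s rule
  expect_true(long$det)
  short <- run(list(c(2.5, 4.0)))           # 1.5-s burst: below it
  expect_false(short$det)
  # burst region has strictly larger mean envelope than baseline
  sel <- round(2.5 * fs):round(5 * fs)
  expect_gt(mean(long$env[sel]), 3 * mean(long$env[round(6 * fs):round(7.9 * fs)]))
  # burst-free signal stays under the burst-calibrated threshold
  expect_lt(stats::quantile(long$benv, 0.99), long$thr$value)
  expect_error(synth_chew_burst(8, list(c(1, 3), c(2, 4)), p), "overlap")
})

test_that("sessions lay ground truth on the protocol timeline", {
  set.seed(42)
  proto <- session_protocol()
  prm <- synthesis_params(fs = 128, seed = 9)
  s <- synth_session(proto, prm)
  ev <- s$events
  expect_equal(sum(ev$label == "gaze"), 30)  # six trials of five cycles
  expect_equal(sum(ev$label == "eb"), 30)
  expect_equal(sum(ev$label == "chew"), 30)
  # each stimulus index appears once per trial
  gaze <- ev[ev$label == "gaze", ]
  expect_equal(as.integer(table(gaze$value)), rep(6L, 5))
  # one-cycle protocol: 22-s timeline
  p1 <- session_protocol(n_trials = 1, cycles_per_trial = 1,
                         stimulus_order = matrix(0L, 1, 1))
  expect_equal(cycle_duration_s(p1), 22)
  s1 <- synth_session(p1, prm)
  expect_equal(duration_s(s1$recording), 22)
  # ground-truth events lie inside their protocol windows
  cyc <- cycle_duration_s(proto)
  starts <- rep(seq(0, proto$n_trials - 1) * (5 * cyc + proto$rest_s),
                each = 5) + rep(0:4 * cyc, proto$n_trials)
  eb <- ev[ev$label == "eb", ]
  expect_true(all(eb$onset_s >= starts + proto$instruction_s - 1e-9 &
                  eb$onset_s + eb$duration_s <=
                    starts + proto$instruction_s + proto$eb_window_s + 1e-9))
  chew <- ev[ev$label == "chew", ]
  cstart <- starts + proto$instruction_s + proto$eb_window_s + proto$food_cue_s +
    proto$gaze_s + proto$chew_cue_s
  expect_true(all(chew$onset_s >= cstart - 1e-9 &
                  chew$onset_s + chew$duration_s <= cstart + proto$chew_s + 1e-9))
})

test_that("identical protocol, params and seed reproduce the session bit-for-bit", {
  proto <- session_protocol(n_trials = 1,
                            stimulus_order = matrix(c(2L, 0L, 4L, 1L, 3L), 1))
  prm <- synthesis_params(fs = 128, seed = 77)
  a <- synth_session(proto, prm)
  b <- synth_session(proto, prm)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
})

test_that("protocol validation enforces permutations and positive durations", {
  expect_error(session_protocol(rest_s = 0), "positive")
  expect_error(session_protocol(n_trials = 1,
                                stimulus_order = matrix(c(0L, 0L, 1L, 2L, 3L), 1)),
               "permutation")
})
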