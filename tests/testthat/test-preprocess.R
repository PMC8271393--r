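# Filtering front-end, re-referencing, windowing and recording I/O.

test_that("make_filter returns the per-modality band edges", {
  eb <- make_filter("eb", 512)
  expect_equal(c(eb$kind, eb$low_hz, eb$high_hz), c("bandpass", 0.5, 5))
  sv <- make_filter("ssvep", 512)
  expect_equal(c(sv$low_hz, sv$high_hz), c(2, 54))
  em <- make_filter("emg", 512)
  expect_equal(em$kind, "highpass")
  expect_equal(em$low_hz, 0.5)
  rt <- make_filter("realtime_common", 128)
  expect_equal(c(rt$low_hz, rt$high_hz), c(0.5, 55))
})

test_that("apply_filter rejects DC, preserves the passband, keeps length", {
  fs <- 512
  sp <- make_filter("eb", fs)
  x <- rep(10, 4 * fs)
  y <- apply_filter(x, sp)
  expect_length(y, length(x))
  # an elliptic bandpass has no DC null, only the -40 dB equiripple floor:
  # 10 uV in -> at most ~0.1 uV out
  expect_lt(max(abs(y)), 0.1)
  t <- (0:(4 * fs - 1)) / fs
  sv <- make_filter("ssvep", fs)
  s <- sin(2 * pi * 9.8 * t)
  ys <- apply_filter(s, sv)
  mid <- (fs):(3 * fs)                     # away from edges
  # zero-phase filtering applies |H|^2: expect sqrt(0.5) * 0.991^2
  expect_equal(sqrt(mean(ys[mid]^2)), sqrt(0.5) * abs(sos_freqz(sv$filter, 9.8)$h)^2,
               tolerance = 0.005)
  expect_lt(abs(mean(apply_filter(s + 7, sv))), 7 * 0.0105)
})

test_that("filtering is linear and causal mode delays rather than anticipates", {
  fs <- 256
  sp <- make_filter("ssvep", fs)
  set.seed(1)
  x <- rnorm(3 * fs); y <- rnorm(3 * fs)
  lhs <- apply_filter(2 * x - 3 * y, sp)
  rhs <- 2 * apply_filter(x, sp) - 3 * apply_filter(y, sp)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # causal response to an impulse is zero before the impulse
  imp <- c(rep(0, fs), 1, rep(0, fs))
  yc <- apply_filter(imp, sp, mode = "causal")
  expect_equal(yc[1:(fs - 1)], rep(0, fs - 1), tolerance = 1e-12)
})

test_that("rereference subtracts the reference exactly and is guarded", {
  fs <- 64
  s <- sin(2 * pi * 3 * (0:(2 * fs - 1)) / fs)
  cz <- rnorm(2 * fs)
  rec <- recording(rbind(cz + s, cz), fs, c("O1", "Cz"))
  rr <- rereference(rec, "O1", "Cz")
  expect_equal(unname(rr$samples["O1", ]), s, tolerance = 1e-12)
  expect_equal(rr$samples["Cz", ], rec$samples["Cz", ])  # ref untouched
  expect_error(rereference(rec, c("O1", "Cz"), "Cz"), "itself")
  expect_error(rereference(rec, "Oz", "Cz"), "missing channel")
})

test_that("sliding_windows produces the step-spaced half-open grid", {
  fs <- 64
  rec <- recording(matrix(rnorm(10 * fs), 1), fs, "FPz")
  w <- sliding_windows(rec, 4, 1)
  expect_length(w, 7)
  expect_equal(vapply(w, function(e) e$window_start_s, 0), 0:6)
  expect_true(all(vapply(w, function(e) ncol(e$samples), 0) == 4 * fs))
  expect_length(sliding_windows(recording(matrix(rnorm(4 * fs), 1), fs, "x"), 4, 1), 1)
  expect_warning(res <- sliding_windows(recording(matrix(rnorm(fs), 1), fs, "x"), 4, 1),
                 "shorter")
  expect_length(res, 0)
})

test_that("CSV and EDF round-trips preserve the recording", {
  set.seed(3)
  rec <- recording(matrix(rnorm(7 * 256, sd = 20), 7), 128,
                   c("FPz", "T7", "T8", "O1", "Oz", "O2", "Cz"))
  fc <- file.path(tempdir(), "rt.csv")
  write_recording(rec, fc)
  rc <- read_recording(fc)
  expect_equal(rc$labels, rec$labels)
  expect_equal(rc$fs, rec$fs)
  expect_equal(unname(rc$samples), unname(rec$samples), tolerance = 1e-6)
  fe <- file.path(tempdir(), "rt.edf")
  write_recording(rec, fe)
  re <- read_recording(fe)
  expect_equal(re$labels, rec$labels)
  expect_equal(re$fs, rec$fs)
  # EDF quantises to 16 bits over the physical range
  qstep <- (max(rec$samples) - min(rec$samples)) / 65535
  expect_lt(max(abs(re$samples - rec$samples)), 2 * qstep)
})

test_that("missing channels and corrupt headers raise named errors", {
  rec <- recording(matrix(rnorm(128), 1), 128, "FPz")
  expect_error(require_channels(rec, "Cz", "SSVEP"), "Cz")
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_recording(bad), "header")
})

test_that("event logs round-trip through TSV", {
  ev <- event_log(c(4.5, 1.2), c(0, 5), c("eb", "gaze"), c(NA, 2))
  p <- file.path(tempdir(), "ev.tsv")
  write_event_log(ev, p)
  back <- read_event_log(p)
  expect_equal(back$onset_s, c(1.2, 4.5))   # ordered by onset
  expect_equal(back$label, c("gaze", "eb"))
  expect_equal(back$value, c(2, NA))
})
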