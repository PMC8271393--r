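# Metrics: Wolpaw ITR, accuracy scoring, FPR, and group averaging.

test_that("itr_wolpaw reproduces known values and limits", {
  expect_equal(itr_wolpaw(0.60, 5, 3), 11.02, tolerance = 1e-2)
  expect_equal(itr_wolpaw(0.8333, 5, 4), 20.08, tolerance = 1e-2)
  expect_equal(itr_wolpaw(0.20, 5, 3), 0, tolerance = 1e-12)   # chance level
  expect_equal(itr_wolpaw(1.0, 5, 4), 15 * log2(5), tolerance = 1e-12)
  expect_equal(itr_wolpaw(0, 2, 1), 60 * (1 + 0), tolerance = 1e-12)  # defined limit
  expect_error(itr_wolpaw(0.5, 1, 3), "classes")
  expect_error(itr_wolpaw(1.2, 5, 3), "0, 1")
})

test_that("itr_wolpaw is continuous and non-decreasing on [1/N, 1]", {
  P <- seq(0.2, 1, by = 0.005)
  v <- itr_wolpaw(P, 5, 4)
  expect_true(all(diff(v) > -1e-12))
  expect_equal(v[1], 0, tolerance = 1e-12)
  expect_equal(v[length(v)], 15 * log2(5), tolerance = 1e-12)
  expect_lt(max(abs(diff(v))), 1)            # no jumps on a fine grid
  # the mutual information is zero at chance and positive on either side,
  # decreasing on [0, 1/N]; raw values are returned unclamped
  Plo <- seq(0, 0.2, by = 0.005)
  vlo <- itr_wolpaw(Plo, 5, 4)
  expect_true(all(diff(vlo) < 1e-12))
  expect_gt(itr_wolpaw(0.1, 5, 4), 0)
})

test_that("accuracy scoring matches window membership and cue identity", {
  truth <- event_log(c(10, 40, 70), c(5, 5, 5),
                     rep("gaze", 3), c(2, 0, 4))
  expect_equal(detection_accuracy(c(2, 0, 4), truth, "ssvep"), 100)
  expect_equal(detection_accuracy(c(2, 1, 1), truth, "ssvep"), 100 / 3)
  expect_equal(detection_accuracy(c(1, 1, 1), truth, "ssvep"), 0)
  # guessing one class against a balanced cue sequence scores chance level
  expect_equal(detection_accuracy(rep(3L, 30),
                                  event_log(1:30, 1, rep("gaze", 30), rep(0:4, 6)),
                                  "ssvep"), 20)
  # 25 of 30 correct -> 83.33 %
  t30 <- event_log(1:30, 1, rep("gaze", 30), rep(0L, 30))
  expect_equal(round(detection_accuracy(c(rep(0L, 25), rep(1L, 5)), t30, "ssvep"), 2),
               83.33)
  tb <- event_log(c(5, 25), c(1, 1), c("eb", "eb"))
  pred <- event_log(5.4, 0, "eb")
  expect_equal(detection_accuracy(pred, tb, "eb"), 50)
  expect_error(detection_accuracy(c(1, 2), truth, "ssvep"), "per cued cycle")
  expect_error(detection_accuracy(pred, event_log(), "eb"), "no ground-truth")
})

test_that("false positive rate counts detections outside allowed windows", {
  ev2 <- event_log(c(100, 400), c(0, 0), c("eb", "eb"))
  expect_equal(round(false_positive_rate(ev2, list(), 10.5), 2), 0.19)
  ev1 <- event_log(200, 0, "chew")
  expect_equal(round(false_positive_rate(ev1, list(), 10.5), 1), 0.1)
  expect_equal(false_positive_rate(event_log(), list(), 10.5), 0)
  # detections inside allowed windows are not false positives
  expect_equal(false_positive_rate(ev2, list(c(90, 110), c(390, 410)), 10.5), 0)
  expect_equal(false_positive_rate(ev2, list(c(90, 110)), 10.5), 1 / 10.5)
  # linear in the count
  evn <- function(k) event_log(seq_len(k) * 10, 0, rep("eb", k))
  expect_equal(false_positive_rate(evn(6), list(), 10.5),
               3 * false_positive_rate(evn(2), list(), 10.5))
})

test_that("group averaging is per-field and averages per-subject ITRs", {
  mk <- function(acc, itr, fpr_eb, fpr_emg)
    metrics_report(c(eb = 90, ssvep = acc, emg = 95), itr,
                   c(eb = fpr_eb, emg = fpr_emg), 30, 10.5)
  reps <- Map(mk, c(60, 60, 86.67, 73.33, 76.67),
              c(11.02, 11.02, 29.78, 19.04, 21.43),
              c(0.19, 0, 0, 0.19, 0.19), c(0.19, 0, 0, 0.1, 0.1))
  avg <- summarize_reports(reps)
  expect_equal(round_half_up(avg$fpr_per_min[["eb"]]), 0.11)
  expect_equal(round_half_up(avg$fpr_per_min[["emg"]]), 0.08)
  expect_equal(round_half_up(avg$itr_bit_per_min), 18.46)
  # the ITR of the mean accuracy is NOT the mean ITR (nonlinearity)
  expect_gt(abs(itr_wolpaw(mean(c(60, 60, 86.67, 73.33, 76.67)) / 100, 5, 3) -
                avg$itr_bit_per_min), 0.05)
  one <- summarize_reports(reps[3])
  expect_equal(one$itr_bit_per_min, 29.78)
  expect_error(summarize_reports(list()), "no reports")
})

test_that("half-up rounding matches table conventions", {
  expect_equal(round_half_up(0.125), 0.13)   # R's half-even round() gives 0.12
  expect_equal(round_half_up(11.0545), 11.05)
  expect_equal(round_half_up(-0.125), -0.13)
})
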