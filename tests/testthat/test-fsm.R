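# Meal-cycle controller: transition table, safety rules, timed exits and
# deterministic replay of the online pipeline.

test_that("single transitions follow the cycle and respect lockouts", {
  cfg <- fsm_config()
  st <- fsm_new()
  r <- fsm_step(st, list(type = "eb", t = 4), cfg)
  expect_equal(r$state$phase, "STIMULATING")
  expect_equal(r$commands$label, "cmd:LED_ON")
  # blink during stimulation: discarded, no command
  r2 <- fsm_step(r$state, list(type = "eb", t = 5), cfg)
  expect_equal(r2$state$phase, "STIMULATING")
  expect_equal(nrow(r2$commands), 0)
  # classification commits the selection
  r3 <- fsm_step(r2$state, list(type = "class", t = 8, value = 2), cfg)
  expect_equal(r3$state$phase, "SELECTING")
  expect_setequal(r3$commands$label, c("cmd:LED_OFF", "cmd:GRAB_FOOD"))
  expect_equal(r3$commands$value[r3$commands$label == "cmd:GRAB_FOOD"], 2)
  # classification outside STIMULATING is ignored (safety)
  r4 <- fsm_step(r3$state, list(type = "class", t = 9, value = 0), cfg)
  expect_equal(r4$state$selection, 2L)
  expect_equal(nrow(r4$commands), 0)
  # grab then feed by timed ticks
  r5 <- fsm_step(r4$state, list(type = "tick", t = 10), cfg)
  expect_equal(r5$state$phase, "FEEDING")
  expect_equal(r5$commands$label, "cmd:FEED")
  r6 <- fsm_step(r5$state, list(type = "tick", t = 12), cfg)
  expect_equal(r6$state$phase, "CHEW_MONITOR")
  # 10 s of silence times the meal out
  r7 <- fsm_step(r6$state, list(type = "tick", t = 22), cfg)
  expect_equal(r7$state$phase, "RETURNING")
  expect_equal(r7$commands$label, "cmd:RETURN_SPOON")
  r8 <- fsm_step(r7$state, list(type = "tick", t = 24), cfg)
  expect_equal(r8$state$phase, "IDLE")
  expect_error(fsm_step(r8$state, list(type = "tick", t = 1), cfg), "sequencing")
  expect_error(fsm_step(fsm_new(), list(type = "bogus", t = 1), cfg), "unknown")
  expect_error(fsm_step(fsm_new(), list(type = "class", t = 1, value = 9), cfg),
               NA)  # ignored outside STIMULATING even if invalid
})

test_that("chew confirmation needs three consecutive window detections", {
  cfg <- fsm_config()
  st <- fsm_new()
  st$phase <- "CHEW_MONITOR"; st$entered_at <- 0
  feed <- function(st, det, t) fsm_step(st, list(type = "chew_window", t = t,
                                                 value = det), cfg)$state
  st <- feed(st, TRUE, 1); st <- feed(st, TRUE, 2)
  expect_equal(st$phase, "CHEW_MONITOR")
  expect_equal(st$chew_confirm_count, 2L)
  st <- feed(st, FALSE, 3)
  expect_equal(st$chew_confirm_count, 0L)    # consecutive rule resets
  st <- feed(st, TRUE, 4); st <- feed(st, TRUE, 5)
  r <- fsm_step(st, list(type = "chew_window", t = 6, value = TRUE), cfg)
  expect_equal(r$state$phase, "RETURNING")
  expect_equal(r$commands$label, "cmd:RETURN_SPOON")
})

test_that("single-cycle replay emits the full command sequence", {
  rec <- single_cycle_recording(fs = 128, seed = 5)
  log <- run_session(rec)
  expect_equal(command_kinds(log),
               c("LED_ON", "LED_OFF", "GRAB_FOOD", "FEED", "RETURN_SPOON"))
  grab <- log[log$label == "cmd:GRAB_FOOD", ]
  expect_equal(grab$value, 2)                # the 9.8-Hz stimulus
  # every command is preceded by its licensing detection
  t_eb <- log$onset_s[log$label == "det:eb"]
  t_led <- log$onset_s[log$label == "cmd:LED_ON"]
  t_cls <- log$onset_s[log$label == "det:class"]
  expect_true(length(t_eb) == 1 && t_eb <= t_led)
  expect_true(all(t_cls <= grab$onset_s))
  chew_det <- log[log$label == "det:chew_window" & log$value == 1, ]
  expect_gte(nrow(chew_det), 3)
  # deterministic replay
  log2 <- run_session(rec)
  expect_identical(as.data.frame(log), as.data.frame(log2))
})

test_that("a blink-free recording never leaves IDLE", {
  rec <- single_cycle_recording(fs = 128, seed = 6)
  # remove the blinks: regenerate FPz as pure background
  rec$samples["FPz", ] <- synth_blink_train(
    0, 0, synthesis_params(fs = 128, seed = 60), duration_s(rec))$signal
  log <- run_session(rec, blink_thr = blink_threshold(40))
  expect_equal(sum(grepl("^cmd:", log$label)), 0)
})

test_that("without chewing the spoon returns on the 10-s timeout", {
  rec <- single_cycle_recording(fs = 128, seed = 5, with_chew = FALSE)
  log <- run_session(rec, emg_thr = emg_threshold(1e6))
  kinds <- command_kinds(log)
  expect_equal(kinds, c("LED_ON", "LED_OFF", "GRAB_FOOD", "FEED", "RETURN_SPOON"))
  t_monitor <- min(log$onset_s[log$label == "state:CHEW_MONITOR"])
  t_return <- log$onset_s[log$label == "cmd:RETURN_SPOON"]
  expect_equal(t_return - t_monitor, 10)
  expect_equal(sum(log$label == "det:chew_window" & log$value == 1), 0)
})

test_that("replay refuses recordings without the montage", {
  rec <- recording(matrix(rnorm(7 * 128), 1), 128, "FPz")
  expect_error(run_session(rec), "missing channel")
})
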