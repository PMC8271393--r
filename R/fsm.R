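# Meal-cycle controller: a finite-state machine over streaming detector
# outputs, emitting abstract robot commands as log events.
#
# Cycle: IDLE --triple blink--> STIMULATING (LED_ON) --SSVEP decision-->
# SELECTING (LED_OFF, GRAB_FOOD) --grab done--> FEEDING (FEED) --feed
# done--> CHEW_MONITOR --triple-confirmed chewing or 10-s timeout-->
# RETURNING (RETURN_SPOON) --return done--> IDLE. Blink events are only
# honoured in IDLE (no activation during meals); classification decisions
# are only honoured in STIMULATING.

#' Controller configuration
#'
#' @param window_s,step_s online analysis window and slide, seconds
#'   (defaults 4 and 1).
#' @param min_stim_s minimum stimulation time before a classification may
#'   commit, seconds (default 4: the first fully-stimulated window).
#' @param grab_s,feed_s simulated robot action durations, seconds.
#' @param return_s simulated spoon-return duration, seconds.
#' @param chew_timeout_s meal ends this many seconds after chew monitoring
#'   starts if chewing is never confirmed (default 10).
#' @param confirm_consecutive require three consecutive chew-window
#'   detections (default TRUE; FALSE allows any three).
#' @param stimuli a \code{stimulus_set}.
#' @param n_harmonics,estimator SSVEP classifier settings.
#' @return a \code{fsm_config} object.
#' @export
fsm_config <- function(window_s = 4, step_s = 1, min_stim_s = 4,
                       grab_s = 2, feed_s = 2, return_s = 2,
                       chew_timeout_s = 10, confirm_consecutive = TRUE,
                       stimuli = stimulus_set(), n_harmonics = 2,
                       estimator = "emsi") {
  structure(list(window_s = window_s, step_s = step_s, min_stim_s = min_stim_s,
                 grab_s = grab_s, feed_s = feed_s, return_s = return_s,
                 chew_timeout_s = chew_timeout_s,
                 confirm_consecutive = confirm_consecutive,
                 stimuli = stimuli, n_harmonics = n_harmonics,
                 estimator = estimator),
            class = "fsm_config")
}

#' Fresh controller state
#'
#' @param t0 start time, seconds.
#' @return an \code{fsm_state}: \code{phase}, \code{entered_at},
#'   \code{selection}, \code{chew_confirm_count}, \code{last_t}.
#' @export
fsm_new <- function(t0 = 0) {
  structure(list(phase = "IDLE", entered_at = t0, selection = NA_integer_,
                 chew_confirm_count = 0L, chew_history = logical(0),
                 last_t = t0),
            class = "fsm_state")
}

#' @export
print.fsm_state <- function(x, ...) {
  cat(sprintf("<fsm_state> %s since %g s%s\n", x$phase, x$entered_at,
              if (!is.na(x$selection)) sprintf(", selection %d", x$selection) else ""))
  invisible(x)
}

.cmd <- function(t, kind, value = NA_real_) {
  event_log(t, 0, paste0("cmd:", kind), value)
}

#' Advance the controller by one input
#'
#' Inputs are detector events or clock ticks, time-ordered:
#' \code{list(type = "eb" | "class" | "chew_window" | "tick", t = seconds,
#' value = ...)}. \code{"class"} carries the chosen stimulus index;
#' \code{"chew_window"} carries a logical window-level chew detection.
#' Blink events outside IDLE and class decisions outside STIMULATING are
#' discarded. Timed transitions (robot action completion, chew timeout)
#' fire on ticks.
#'
#' @param state an \code{fsm_state}.
#' @param input the input event.
#' @param config an \code{fsm_config}.
#' @return list with the new \code{state} and an \code{event_log} of
#'   emitted \code{cmd:*} events.
#' @export
fsm_step <- function(state, input, config) {
  stopifnot(inherits(state, "fsm_state"), inherits(config, "fsm_config"))
  t <- input$t
  if (t < state$last_t) {
    stop("sequencing error: input at t = ", t, " after t = ", state$last_t)
  }
  state$last_t <- t
  cmds <- event_log()
  goto <- function(phase) {
    state$phase <<- phase
    state$entered_at <<- t
  }
  # timed progressions first (they may be due exactly at this tick)
  if (state$phase == "SELECTING" && t - state$entered_at >= config$grab_s) {
    cmds <- bind_events(cmds, .cmd(t, "FEED"))
    goto("FEEDING")
  }
  if (state$phase == "FEEDING" && t - state$entered_at >= config$feed_s) {
    goto("CHEW_MONITOR")
    state$chew_history <- logical(0)
    state$chew_confirm_count <- 0L
  }
  if (state$phase == "CHEW_MONITOR" && t - state$entered_at >= config$chew_timeout_s) {
    cmds <- bind_events(cmds, .cmd(t, "RETURN_SPOON"))
    goto("RETURNING")
  }
  if (state$phase == "RETURNING" && t - state$entered_at >= config$return_s) {
    goto("IDLE")
    state$selection <- NA_integer_
  }
  # event handling
  if (input$type == "eb") {
    if (state$phase == "IDLE") {
      cmds <- bind_events(cmds, .cmd(t, "LED_ON"))
      goto("STIMULATING")
    }                                    # else: discarded (lockout)
  } else if (input$type == "class") {
    if (state$phase == "STIMULATING") {
      idx <- as.integer(input$value)
      if (is.na(idx) || idx < 0 || idx >= length(config$stimuli$freqs_hz)) {
        stop("class decision carries invalid stimulus index: ", input$value)
      }
      state$selection <- idx
      cmds <- bind_events(cmds, .cmd(t, "LED_OFF"), .cmd(t, "GRAB_FOOD", idx))
      goto("SELECTING")
    }
  } else if (input$type == "chew_window") {
    if (state$phase == "CHEW_MONITOR") {
      state$chew_history <- c(state$chew_history, isTRUE(input$value))
      state$chew_confirm_count <- if (config$confirm_consecutive) {
        n <- length(state$chew_history)
        k <- 0L
        while (k < 3L && k < n && state$chew_history[n - k]) k <- k + 1L
        min(k, 3L)
      } else min(3L, sum(state$chew_history))
      if (realtime_chew_confirm(state$chew_history, config$confirm_consecutive)) {
        cmds <- bind_events(cmds, .cmd(t, "RETURN_SPOON"))
        goto("RETURNING")
      }
    }
  } else if (input$type != "tick") {
    stop("unknown input type: ", input$type)
  }
  list(state = state, commands = cmds)
}

#' Replay a recording through the full online pipeline
#'
#' Filters the recording with the shared online bandpass (causally), slides
#' the analysis window, runs the three detectors gated by the controller
#' phase (blink detection only in IDLE, classification only in
#' STIMULATING, chew detection only in CHEW_MONITOR), and drives the state
#' machine. The replay is deterministic: the same recording and
#' configuration yield an identical log.
#'
#' @param rec a \code{bci_recording} with channels FPz, T7, T8, O1, Oz,
#'   O2, Cz.
#' @param config an \code{fsm_config}.
#' @param blink_thr,emg_thr thresholds; if \code{NULL} they are calibrated
#'   from the recording itself: half the mean detected blink amplitude,
#'   and half the median envelope of the loudest 5-s segment (standing in
#'   for an instructed chewing calibration).
#' @param occipital channels used for classification (default all three).
#' @return an \code{event_log} containing detections (\code{det:*}),
#'   commands (\code{cmd:*}) and state entries (\code{state:*}).
#' @export
run_session <- function(rec, config = fsm_config(), blink_thr = NULL,
                        emg_thr = NULL, occipital = c("O1", "Oz", "O2")) {
  stopifnot(inherits(rec, "bci_recording"))
  require_channels(rec, c("FPz", "T7", "T8", occipital, "Cz"), "session replay")
  common <- make_filter("realtime_common", rec$fs)
  filt <- apply_filter(rec, common, mode = "causal")
  fpz <- filt$samples["FPz", ]
  if (is.null(blink_thr)) blink_thr <- calibrate_blink_threshold(fpz, rec$fs)
  env7 <- emg_envelope(filt$samples["T7", ], rec$fs)
  env8 <- emg_envelope(filt$samples["T8", ], rec$fs)
  if (is.null(emg_thr)) {
    # the chew threshold is half the median of a *chewing* calibration
    # segment; stand in for the instructed calibration with the loudest
    # 5-s span of the combined envelope
    comb <- pmax(env7, env8)
    w <- min(length(comb), round(5 * rec$fs))
    cs <- c(0, cumsum(comb))
    means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
    i0 <- which.max(means)
    emg_thr <- calibrate_emg_threshold(comb[i0:(i0 + w - 1)])
  }
  occ <- rereference(filt, occipital, "Cz")
  n_win <- floor((duration_s(rec) - config$window_s) / config$step_s) + 1
  if (n_win < 1) stop("recording shorter than one analysis window")
  state <- fsm_new(0)
  log <- event_log()
  last_eb <- -Inf
  for (w in seq_len(n_win)) {
    t0 <- (w - 1) * config$step_s
    te <- t0 + config$window_s
    i <- round(t0 * rec$fs) + 1
    j <- round(te * rec$fs)
    inputs <- list()
    if (state$phase == "IDLE") {
      dec <- detect_triple_blink(fpz[i:j], rec$fs, blink_thr)
      if (dec$detected) {
        mid <- t0 + dec$peak_times_s[2]
        if (mid - last_eb >= 1) {
          last_eb <- mid
          log <- bind_events(log, event_log(mid, 0, "det:eb"))
          inputs <- c(inputs, list(list(type = "eb", t = te)))
        }
      }
    } else if (state$phase == "STIMULATING" &&
               te - state$entered_at >= config$min_stim_s) {
      cd <- classify_ssvep(occ$samples[occipital, i:j, drop = FALSE], rec$fs,
                           config$stimuli, config$n_harmonics, config$estimator)
      log <- bind_events(log, event_log(te, 0, "det:class", cd$chosen_index))
      inputs <- c(inputs, list(list(type = "class", t = te, value = cd$chosen_index)))
    } else if (state$phase == "CHEW_MONITOR") {
      env <- rbind(env7[i:j], env8[i:j])
      ch <- detect_chewing(env, rec$fs, emg_thr)
      log <- bind_events(log, event_log(te, 0, "det:chew_window",
                                        as.numeric(ch$detected)))
      inputs <- c(inputs, list(list(type = "chew_window", t = te,
                                    value = ch$detected)))
    }
    inputs <- c(inputs, list(list(type = "tick", t = te)))
    for (inp in inputs) {
      prev <- state$phase
      res <- fsm_step(state, inp, config)
      state <- res$state
      log <- bind_events(log, res$commands)
      if (state$phase != prev) {
        log <- bind_events(log, event_log(inp$t, 0, paste0("state:", state$phase)))
      }
    }
  }
  log
}
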