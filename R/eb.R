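# Triple eye-blink activation detector (prefrontal FPz).
#
# A deliberate triple blink switches the system on. Detection screens
# candidate peaks on the 0.5-5 Hz filtered FPz trace: exactly three peaks
# above the subject threshold with both inter-peak intervals strictly
# inside (0.3, 0.8) s. If the direct pass finds no qualifying triple, a
# continuous-wavelet pass (Ricker kernel spanning blink widths) re-locates
# candidate peaks and the same screening is repeated.

# strict local maxima above min_height; peaks closer than min_dist samples
# to a larger accepted peak are suppressed (strictly closer, so a pair at
# exactly the minimum distance survives for the interval screen to judge).
.find_peaks <- function(x, min_height = -Inf, min_dist = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] > min_height]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

# Ricker (Mexican-hat) wavelet, unit L2 norm
.ricker <- function(len, a) {
  t <- seq_len(len) - (len + 1) / 2
  w <- (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
  w / sqrt(sum(w^2))
}

# scale-averaged CWT trace, normalised so that a blink-like pulse of
# amplitude A yields a trace peak of ~A (the zero-mean Ricker kernels
# also cancel the slow baseline undershoot of the blink bandpass, which
# is what makes the rescue pass recover borderline peaks)
.cwt_trace <- function(x, fs, width_range_s = c(0.1, 0.4), n_scales = 6) {
  widths <- exp(seq(log(width_range_s[1]), log(width_range_s[2]), length.out = n_scales))
  bank <- function(v) {
    acc <- numeric(length(v))
    for (w in widths) {
      a <- w * fs / 4                        # main lobe of the Ricker ~ 4a
      len <- min(length(v), 2 * ceiling(5 * a) + 1)
      k <- .ricker(len, a)
      cv <- stats::filter(v, k, method = "convolution", sides = 2)
      cv[is.na(cv)] <- 0
      acc <- acc + as.numeric(cv)
    }
    acc / length(widths)
  }
  # gain calibration: unit raised-cosine pulse at the mid width
  wm <- sqrt(prod(range(widths)))
  np <- 2 * round(wm * fs) + 1
  tt <- (seq_len(np) - (np + 1) / 2) / fs
  pulse <- ifelse(abs(tt / wm) < 0.5, 0.5 * (1 + cos(2 * pi * tt / wm)), 0)
  gain <- max(bank(pulse))
  bank(x) / gain
}

#' Calibrate the blink amplitude threshold
#'
#' The subject threshold is half the mean amplitude of the blinks detected
#' in a calibration pass (an instructed-blink recording filtered with the
#' blink bandpass).
#'
#' @param calibration_signal filtered FPz signal containing instructed
#'   blinks, microvolts.
#' @param fs sampling rate, Hz.
#' @return a \code{blink_threshold} object (\code{value} in microvolts,
#'   \code{source = "calibration"}).
#' @examples
#' p <- synthesis_params(noise_rms_uv = 0, seed = 1)
#' b <- synth_blink_train(3, 0.6, p, 5)
#' calibrate_blink_threshold(b$signal, 512)$value  # ~50
#' @export
calibrate_blink_threshold <- function(calibration_signal, fs) {
  floor_ <- 5 * stats::mad(calibration_signal)
  pk <- .find_peaks(calibration_signal, min_height = floor_,
                    min_dist = round(0.3 * fs))
  if (length(pk) == 0) {
    stop("calibration error: no blink peaks found in the calibration signal")
  }
  blink_threshold(mean(calibration_signal[pk]) / 2, source = "calibration")
}

#' @rdname calibrate_blink_threshold
#' @param value threshold in microvolts (> 0).
#' @param source \code{"calibration"} or \code{"manual"}.
#' @export
blink_threshold <- function(value, source = "manual") {
  if (!is.numeric(value) || value <= 0) stop("blink threshold must be positive")
  structure(list(value = value, source = source), class = "blink_threshold")
}

# screen peak indices: exactly three supra-threshold peaks with both gaps
# strictly inside (0.3, 0.8) s
.screen_triple <- function(pk, fs) {
  if (length(pk) != 3) return(FALSE)
  gaps <- diff(pk) / fs
  all(gaps > 0.3 & gaps < 0.8)
}

#' Detect a triple eye-blink in an epoch
#'
#' Applies the four screening conditions: (1) exactly three supra-threshold
#' peaks; (2) both inter-peak intervals strictly inside (0.3, 0.8) s;
#' (3) if no triple is found, peaks are re-located on a scale-averaged
#' Ricker-wavelet trace, normalised so a blink-width pulse keeps its
#' amplitude (the zero-mean kernels also cancel the bandpass baseline
#' undershoot that depresses late peaks); and (4) conditions (1)-(2) are
#' re-applied to the rescued peaks with the same threshold.
#'
#' @param x filtered FPz epoch (numeric vector or single-channel
#'   \code{bci_epoch}), microvolts.
#' @param fs sampling rate, Hz (taken from the epoch if one is given).
#' @param thr a \code{blink_threshold}.
#' @return a \code{blink_decision}: \code{detected}, \code{peak_times_s}
#'   (relative to epoch start), \code{peak_amplitudes_uv},
#'   \code{rescued_by_cwt}.
#' @export
detect_triple_blink <- function(x, fs, thr) {
  if (inherits(x, "bci_epoch")) {
    fs <- x$fs
    x <- as.numeric(x$samples[1, ])
  }
  stopifnot(inherits(thr, "blink_threshold"))
  mind <- round(0.3 * fs)
  pk <- .find_peaks(x, min_height = thr$value, min_dist = mind)
  detected <- .screen_triple(pk, fs)
  rescued <- FALSE
  if (!detected) {
    trace <- .cwt_trace(x, fs)
    cpk <- .find_peaks(trace, min_height = thr$value, min_dist = mind)
    if (length(cpk)) {
      # the filter-bank trace can bias a peak location by a sample when
      # neighbouring responses overlap; snap timing back to the signal's
      # local maximum (+/- 50 ms) while keeping the trace amplitudes
      half <- max(1L, round(0.05 * fs))
      cpk_snap <- vapply(cpk, function(i) {
        lo <- max(1, i - half); hi <- min(length(x), i + half)
        as.numeric(lo + which.max(x[lo:hi]) - 1)
      }, 0)
      if (.screen_triple(cpk_snap, fs)) {
        pk <- cpk_snap
        detected <- TRUE
        rescued <- TRUE
        trace_amps <- trace[cpk]
      }
    }
  }
  amps <- if (length(pk) == 0) numeric(0) else if (rescued) trace_amps else x[pk]
  structure(list(detected = detected,
                 peak_times_s = (pk - 1) / fs,
                 peak_amplitudes_uv = amps,
                 rescued_by_cwt = rescued),
            class = "blink_decision")
}

#' @export
print.blink_decision <- function(x, ...) {
  cat(sprintf("<blink_decision> %s%s; %d peak(s)%s\n",
              if (x$detected) "TRIPLE BLINK" else "no triple blink",
              if (x$rescued_by_cwt) " (wavelet rescue)" else "",
              length(x$peak_times_s),
              if (length(x$peak_times_s)) paste0(" at ",
                paste(sprintf("%.2f", x$peak_times_s), collapse = ", "), " s") else ""))
  invisible(x)
}

#' Scan a sliding-window stream for triple blinks
#'
#' Runs \code{\link{detect_triple_blink}} over ordered windows, suppresses
#' windows flagged locked-out (blink detection is disabled during meals),
#' and deduplicates detections that the overlapping 4-s windows report more
#' than once: events whose middle-peak times differ by less than
#' \code{dedup_s} are merged.
#'
#' @param windows list of single-channel \code{bci_epoch} in temporal order
#'   (e.g. from \code{\link{sliding_windows}} on the filtered FPz channel).
#' @param thr a \code{blink_threshold}.
#' @param lockout logical vector, one flag per window; \code{TRUE} windows
#'   never emit (default none).
#' @param dedup_s merge radius on middle-peak time, seconds (default 1).
#' @return an \code{event_log} of \code{"eb"} events; onset is the
#'   middle-peak time on the recording timeline.
#' @export
scan_stream_for_eb <- function(windows, thr, lockout = rep(FALSE, length(windows)),
                               dedup_s = 1) {
  if (length(lockout) != length(windows)) {
    stop("need one lockout flag per window")
  }
  times <- numeric(0)
  for (i in seq_along(windows)) {
    if (lockout[i]) next
    dec <- detect_triple_blink(windows[[i]], fs = NULL, thr = thr)
    if (dec$detected) {
      mid <- windows[[i]]$window_start_s + dec$peak_times_s[2]
      if (length(times) == 0 || all(abs(times - mid) >= dedup_s)) {
        times <- c(times, mid)
      }
    }
  }
  event_log(times, rep(0, length(times)), rep("eb", length(times)))
}
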