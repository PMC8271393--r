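# Chewing detection from temporal-channel EMG (T7, T8).
#
# The envelope is the rectify-smooth-differentiate-rectify-smooth chain:
# MA(|diff(MA(|x|))|). Chewing is reported when the envelope exceeds the
# subject threshold (half the median calibration envelope) for strictly
# more than 2 s worth of samples (1024 at 512 Hz, 256 at 128 Hz). The
# online path additionally requires three consecutive window detections
# before a meal cycle is closed (spoon-descent safety).

# centered moving average, edge-padded to keep length
.moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  cs <- cumsum(xp)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  i <- seq_len(n) + w
  (cs[i + half_hi] - cs[i - half_lo - 1]) / w
}

#' Chewing-EMG envelope
#'
#' \code{MA(|diff(MA(|x|))|)}: rectify, smooth, first-difference (scaled by
#' fs), rectify, smooth. Output has the input length (edge-padded) and is
#' non-negative.
#'
#' @param x highpass-filtered temporal-channel signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param ma_window_s moving-average window for both smoothing steps,
#'   seconds (default 0.25).
#' @return envelope signal, same length as \code{x}.
#' @export
emg_envelope <- function(x, fs, ma_window_s = 0.25) {
  if (ma_window_s <= 0) stop("ma_window_s must be positive")
  w <- round(ma_window_s * fs)
  if (length(x) <= 2 * w) stop("signal shorter than twice the smoothing window")
  m1 <- .moving_avg(abs(x), w)
  d <- c(diff(m1), 0) * fs
  .moving_avg(abs(d), w)
}

#' Calibrate the chewing threshold
#'
#' The subject threshold is 50\% of the median calibration envelope.
#'
#' @param calibration_envelope envelope of a calibration segment that
#'   contains chewing (from \code{\link{emg_envelope}}).
#' @return an \code{emg_threshold} object.
#' @examples
#' calibrate_emg_threshold(c(1, 2, 3, 4, 100))$value  # 1.5
#' @export
calibrate_emg_threshold <- function(calibration_envelope) {
  if (length(calibration_envelope) == 0) stop("empty calibration envelope")
  emg_threshold(stats::median(calibration_envelope) / 2, source = "calibration")
}

#' @rdname calibrate_emg_threshold
#' @param value threshold in envelope units (> 0).
#' @param source \code{"calibration"} or \code{"manual"}.
#' @export
emg_threshold <- function(value, source = "manual") {
  if (!is.numeric(value) || value <= 0) stop("EMG threshold must be positive")
  structure(list(value = value, source = source), class = "emg_threshold")
}

#' Detect chewing from an envelope
#'
#' Counts samples with \code{envelope > threshold}; chewing is detected iff
#' the count strictly exceeds \code{min_duration_s * fs} (1024 samples at
#' 512 Hz -- a count of exactly 1024 is \emph{not} a detection).
#'
#' @param envelope envelope signal (one channel), or a channels-by-time
#'   matrix of envelopes (T7 and T8), in which case the per-sample maximum
#'   across channels is thresholded and per-channel counts are reported.
#' @param fs sampling rate, Hz.
#' @param thr an \code{emg_threshold}.
#' @param min_duration_s minimum supra-threshold duration, seconds
#'   (default 2).
#' @return a \code{chew_decision}: \code{detected}, \code{supra_count},
#'   \code{required_count}, \code{per_channel_counts}.
#' @export
detect_chewing <- function(envelope, fs, thr, min_duration_s = 2) {
  stopifnot(inherits(thr, "emg_threshold"))
  if (is.vector(envelope)) envelope <- matrix(envelope, nrow = 1)
  if (any(envelope < 0)) stop("envelope must be non-negative")
  per_ch <- apply(envelope, 1, function(e) sum(e > thr$value))
  combined <- apply(envelope, 2, max)
  supra <- sum(combined > thr$value)
  required <- round(min_duration_s * fs)
  structure(list(detected = supra > required,
                 supra_count = supra,
                 required_count = required,
                 per_channel_counts = per_ch),
            class = "chew_decision")
}

#' @export
print.chew_decision <- function(x, ...) {
  cat(sprintf("<chew_decision> %s: %d supra-threshold samples (need > %d)\n",
              if (x$detected) "CHEWING" else "no chewing",
              x$supra_count, x$required_count))
  invisible(x)
}

#' Online triple-confirmation rule for chewing
#'
#' The real-time criterion is stricter than the offline one: the 2-s rule
#' must fire in three sliding windows before the cycle ends. By default the
#' three detections must be consecutive.
#'
#' @param window_decisions list of \code{chew_decision} (or a logical
#'   vector) in temporal order since chew monitoring began.
#' @param consecutive require three in a row (default \code{TRUE}); if
#'   \code{FALSE}, any three detections confirm.
#' @return \code{TRUE} once chewing is confirmed.
#' @examples
#' realtime_chew_confirm(c(TRUE, TRUE, TRUE))        # TRUE
#' realtime_chew_confirm(c(TRUE, TRUE, FALSE, TRUE)) # FALSE
#' @export
realtime_chew_confirm <- function(window_decisions, consecutive = TRUE) {
  det <- if (is.logical(window_decisions)) window_decisions else
    vapply(window_decisions, function(d) isTRUE(d$detected), FALSE)
  if (length(det) < 3) return(FALSE)
  if (!consecutive) return(sum(det) >= 3)
  runs <- rle(det)
  any(runs$values & runs$lengths >= 3)
}
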