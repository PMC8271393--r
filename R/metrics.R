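# Performance metrics: per-modality accuracy, Wolpaw information transfer
# rate and false-positive rate over the session.

#' Wolpaw information transfer rate
#'
#' \deqn{ITR = (60/T) [\log_2 N + P \log_2 P + (1-P) \log_2((1-P)/(N-1))]}
#' bits per minute for an N-class selection with accuracy P and selection
#' time T seconds. The defined limits are used at P = 0 and P = 1
#' (\eqn{0 \log 0 \equiv 0}). The formula is a symmetric-channel mutual
#' information: it is zero exactly at chance (P = 1/N) and positive on
#' either side; the raw value is always returned, never clamped.
#'
#' @param P probability of correct selection, in [0, 1]; vectorised.
#' @param N number of classes (>= 2; 5 stimuli here).
#' @param T_seconds selection time in seconds (the epoch length, 3 or 4);
#'   vectorised alongside \code{P}.
#' @return ITR in bits per minute.
#' @examples
#' itr_wolpaw(0.60, 5, 3)     # 11.02
#' itr_wolpaw(0.8333, 5, 4)   # 20.08
#' itr_wolpaw(1, 5, 4)        # 15 * log2(5)
#' @export
itr_wolpaw <- function(P, N = 5, T_seconds = 4) {
  if (N < 2) stop("ITR needs at least 2 classes")
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  if (any(T_seconds <= 0)) stop("selection time must be positive")
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(N) + xlx(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
  (60 / T_seconds) * bits
}

#' Score detections against ground truth
#'
#' For the blink and chewing modalities a cycle is correct when a detection
#' falls inside the cycle's ground-truth window; for SSVEP a cycle is
#' correct when the chosen stimulus index equals the cued one.
#'
#' @param pred for \code{"eb"}/\code{"emg"}: an \code{event_log} of
#'   detections; for \code{"ssvep"}: an integer vector of chosen 0-based
#'   indices (or an \code{event_log} whose \code{value} carries them), one
#'   per cycle in cue order.
#' @param truth ground-truth \code{event_log}: \code{eb}/\code{chew}
#'   windows, or \code{gaze} events whose \code{value} is the cued index.
#' @param modality \code{"eb"}, \code{"ssvep"} or \code{"emg"}.
#' @param pad_s tolerance added on both sides of a ground-truth window
#'   (default 0).
#' @return accuracy in percent.
#' @export
detection_accuracy <- function(pred, truth, modality = c("eb", "ssvep", "emg"),
                               pad_s = 0) {
  modality <- match.arg(modality)
  lab <- switch(modality, eb = "eb", emg = "chew", ssvep = "gaze")
  tw <- truth[truth$label == lab, , drop = FALSE]
  if (nrow(tw) == 0) stop("no ground-truth cycles for modality ", modality)
  if (modality == "ssvep") {
    chosen <- if (inherits(pred, "event_log") || is.data.frame(pred)) pred$value else pred
    if (length(chosen) != nrow(tw)) {
      stop("need one chosen index per cued cycle (", nrow(tw), "), got ", length(chosen))
    }
    return(100 * mean(chosen == tw$value))
  }
  hit <- vapply(seq_len(nrow(tw)), function(i) {
    any(pred$onset_s >= tw$onset_s[i] - pad_s &
        pred$onset_s <= tw$onset_s[i] + tw$duration_s[i] + pad_s)
  }, FALSE)
  100 * mean(hit)
}

#' False-positive rate over the session
#'
#' Detections outside every allowed (task) window count as false positives;
#' the rate is per minute of the whole experimental period.
#'
#' @param detections an \code{event_log} of detections.
#' @param allowed_windows list of \code{c(start, stop)} spans in seconds
#'   during which a detection is legitimate.
#' @param session_minutes duration of the scored period, minutes (10.5 for
#'   the offline evaluation).
#' @return false positives per minute.
#' @examples
#' ev <- event_log(c(10, 300), c(0, 0), c("eb", "eb"))
#' false_positive_rate(ev, list(), 10.5)  # 2/10.5
#' @export
false_positive_rate <- function(detections, allowed_windows, session_minutes) {
  if (session_minutes <= 0) stop("session_minutes must be positive")
  if (nrow(detections) == 0) return(0)
  ok <- rep(FALSE, nrow(detections))
  for (w in allowed_windows) {
    ok <- ok | (detections$onset_s >= w[1] & detections$onset_s <= w[2])
  }
  sum(!ok) / session_minutes
}

#' Per-subject metrics report
#'
#' @param accuracy_pct named numeric: accuracy per modality, percent.
#' @param itr_bit_per_min SSVEP information transfer rate, bits/min.
#' @param fpr_per_min named numeric: false-positive rate per modality
#'   (\code{eb}, \code{emg}), times/min.
#' @param n_cycles number of scored cycles.
#' @param session_minutes scored period, minutes.
#' @return a \code{metrics_report} object.
#' @export
metrics_report <- function(accuracy_pct, itr_bit_per_min, fpr_per_min,
                           n_cycles, session_minutes) {
  if (any(accuracy_pct < 0 | accuracy_pct > 100)) stop("accuracy must be in [0, 100]")
  if (any(fpr_per_min < 0)) stop("FPR must be non-negative")
  structure(list(accuracy_pct = accuracy_pct,
                 itr_bit_per_min = itr_bit_per_min,
                 fpr_per_min = fpr_per_min,
                 n_cycles = n_cycles,
                 session_minutes = session_minutes),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("  accuracy (%):", paste(sprintf("%s %.2f", names(x$accuracy_pct),
                                       x$accuracy_pct), collapse = ", "), "\n")
  cat(sprintf("  ITR (bit/min): %.2f\n", x$itr_bit_per_min))
  cat("  FPR (times/min):", paste(sprintf("%s %.2f", names(x$fpr_per_min),
                                          x$fpr_per_min), collapse = ", "), "\n")
  cat(sprintf("  %d cycles over %.2f min\n", x$n_cycles, x$session_minutes))
  invisible(x)
}

#' Average per-subject reports
#'
#' Fields are averaged arithmetically; the group ITR is the mean of the
#' per-subject ITRs (not the ITR of the mean accuracy -- the two differ
#' because the ITR is nonlinear in P).
#'
#' @param reports non-empty list of \code{metrics_report}.
#' @return a \code{metrics_report} of averages.
#' @export
summarize_reports <- function(reports) {
  if (length(reports) == 0) stop("no reports to summarize")
  avg <- function(field) {
    Reduce(`+`, lapply(reports, `[[`, field)) / length(reports)
  }
  metrics_report(avg("accuracy_pct"),
                 mean(vapply(reports, function(r) r$itr_bit_per_min, 0)),
                 avg("fpr_per_min"),
                 mean(vapply(reports, function(r) r$n_cycles, 0)),
                 mean(vapply(reports, function(r) r$session_minutes, 0)))
}

#' Round half-up to table precision
#'
#' Report tables round half-up at two decimals (R's \code{round} rounds
#' half-even).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Published five-subject reference results
#'
#' The per-subject SSVEP accuracies and ITRs of the five-subject
#' evaluation, by condition (1 or 3 occipital channels, 3-s or 4-s
#' epochs), and the per-subject blink/chewing false-positive rates over
#' the 10.5-min session. Bundled as printed inputs for cross-checking the
#' metrics implementation.
#'
#' @return \code{reference_performance()}: data frame with columns
#'   \code{condition}, \code{n_channels}, \code{epoch_s}, \code{subject},
#'   \code{accuracy_pct}, \code{itr_bit_per_min}.
#'   \code{reference_fpr()}: data frame with \code{modality},
#'   \code{subject}, \code{fpr_per_min}.
#' @export
reference_performance <- function() {
  utils::read.delim(system.file("extdata", "reference_performance.tsv",
                                package = "mealbci"), stringsAsFactors = FALSE)
}

#' @rdname reference_performance
#' @export
reference_fpr <- function() {
  utils::read.delim(system.file("extdata", "reference_fpr.tsv",
                                package = "mealbci"), stringsAsFactors = FALSE)
}
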