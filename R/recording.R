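# Multichannel recording and epoch containers.

#' Construct a multichannel scalp recording
#'
#' A \code{bci_recording} holds a channels-by-time matrix in microvolts plus
#' its sampling rate and ordered channel labels. The channel montage used
#' throughout the package is \code{FPz} (blinks), \code{T7}/\code{T8}
#' (chewing EMG), \code{O1}/\code{Oz}/\code{O2} (SSVEP) and \code{Cz}
#' (SSVEP reference).
#'
#' @param samples numeric matrix, one row per channel, microvolts.
#' @param fs sampling rate, Hz.
#' @param labels character vector of unique channel names, one per row.
#' @param start_time recording start offset in seconds (default 0).
#' @return a \code{bci_recording} object.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 512), 2), fs = 512, labels = c("FPz", "Cz"))
#' rec
#' @export
recording <- function(samples, fs, labels, start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(labels) != nrow(samples)) {
    stop("got ", length(labels), " labels for ", nrow(samples), " channel rows")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = as.character(labels),
                 start_time = start_time),
            class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples (%.2f s at %g Hz)\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a \code{bci_recording}.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Extract one channel as a numeric vector
#' @param rec a \code{bci_recording}.
#' @param name channel label.
#' @return the channel samples, microvolts.
#' @export
channel_data <- function(rec, name) {
  require_channels(rec, name)
  rec$samples[name, ]
}

#' Check that named channels are present
#'
#' @param rec a \code{bci_recording}.
#' @param channels channel labels that must exist.
#' @param purpose optional string naming the pipeline that needs them, for
#'   the error message.
#' @return invisibly \code{TRUE}; stops with a named-channel error otherwise.
#' @export
require_channels <- function(rec, channels, purpose = NULL) {
  missing <- setdiff(channels, rec$labels)
  if (length(missing) > 0) {
    stop("missing channel(s) ", paste(missing, collapse = ", "),
         if (!is.null(purpose)) paste0(" required for ", purpose),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Re-reference channels by subtracting a reference channel
#'
#' The SSVEP path re-references the occipital channels by subtracting Cz,
#' which suppresses activity common to both sites.
#'
#' @param rec a \code{bci_recording}.
#' @param channels channels to re-reference.
#' @param ref reference channel name (must not be among \code{channels}).
#' @return the recording with \code{channels} replaced by
#'   \code{channel - ref}; other channels untouched.
#' @examples
#' rec <- recording(matrix(1:8, 2, byrow = TRUE), 4, c("O1", "Cz"))
#' rereference(rec, "O1", "Cz")$samples["O1", ]
#' @export
rereference <- function(rec, channels, ref) {
  require_channels(rec, c(channels, ref), "re-referencing")
  if (ref %in% channels) stop("reference channel ", ref, " cannot be re-referenced against itself")
  for (ch in channels) {
    rec$samples[ch, ] <- rec$samples[ch, ] - rec$samples[ref, ]
  }
  rec
}

#' Cut a fixed epoch out of a recording
#'
#' Windows are half-open \code{[start, start + len)} in seconds from
#' recording start.
#'
#' @param rec a \code{bci_recording}.
#' @param start_s window start, seconds.
#' @param len_s window length, seconds.
#' @param channels optional channel subset (default all).
#' @return a \code{bci_epoch}: samples, fs, labels, \code{window_start_s},
#'   \code{window_len_s}.
#' @export
epoch_at <- function(rec, start_s, len_s, channels = rec$labels) {
  require_channels(rec, channels)
  i0 <- round(start_s * rec$fs) + 1
  n <- round(len_s * rec$fs)
  if (i0 < 1 || i0 + n - 1 > ncol(rec$samples)) {
    stop("epoch [", start_s, ", ", start_s + len_s, ") s exceeds the recording")
  }
  structure(list(samples = rec$samples[channels, i0:(i0 + n - 1), drop = FALSE],
                 fs = rec$fs, labels = channels,
                 window_start_s = start_s, window_len_s = len_s),
            class = "bci_epoch")
}

#' @export
print.bci_epoch <- function(x, ...) {
  cat(sprintf("<bci_epoch> [%g, %g) s, %d channel(s) at %g Hz\n",
              x$window_start_s, x$window_start_s + x$window_len_s,
              nrow(x$samples), x$fs))
  invisible(x)
}

#' Sliding analysis windows over a recording
#'
#' The online system analyses a 4-s window advanced by 1 s; the offline
#' replay uses the same grid. Window starts are 0, step, 2*step, ...;
#' the count is \code{floor((T - window) / step) + 1}.
#'
#' @param rec a \code{bci_recording}.
#' @param window_s window length, seconds (default 4).
#' @param step_s slide, seconds (default 1).
#' @param channels optional channel subset.
#' @return a list of \code{bci_epoch}; empty (with a warning) if the
#'   recording is shorter than one window.
#' @examples
#' rec <- recording(matrix(rnorm(10 * 64), 1), 64, "FPz")
#' length(sliding_windows(rec, 4, 1))  # 7
#' @export
sliding_windows <- function(rec, window_s = 4, step_s = 1, channels = rec$labels) {
  T <- duration_s(rec)
  if (T < window_s) {
    warning("recording (", T, " s) shorter than one ", window_s, "-s window")
    return(list())
  }
  n_win <- floor((T - window_s) / step_s) + 1
  starts <- (seq_len(n_win) - 1) * step_s
  lapply(starts, function(s) epoch_at(rec, s, window_s, channels))
}
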