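# Per-modality filter specifications and filtering front-end.

#' Build the filter specification for a signal modality
#'
#' Returns the elliptic IIR filter used by each processing path:
#' \describe{
#'   \item{\code{eb}}{eye-blink path, bandpass 0.5--5 Hz (prefrontal FPz)}
#'   \item{\code{ssvep}}{occipital path, bandpass 2--54 Hz (keeps the
#'     stimulus band and its harmonics, rejects 60-Hz line noise)}
#'   \item{\code{emg}}{temporal chewing path, highpass 0.5 Hz (DC removal)}
#'   \item{\code{realtime_common}}{the single shared online filter,
#'     bandpass 0.5--55 Hz}
#' }
#'
#' @param modality one of \code{"eb"}, \code{"ssvep"}, \code{"emg"},
#'   \code{"realtime_common"}.
#' @param fs sampling rate in Hz (512 offline, 128 online; any rate above
#'   twice the upper band edge is accepted).
#' @param order elliptic prototype order (default 4).
#' @param rp passband ripple in dB (default 0.5).
#' @param rs stopband attenuation in dB (default 40).
#' @return a \code{filter_spec} object (kind, band edges, design parameters
#'   and the realised second-order sections).
#' @examples
#' make_filter("eb", 512)
#' make_filter("realtime_common", 128)
#' @export
make_filter <- function(modality = c("eb", "ssvep", "emg", "realtime_common"),
                        fs, order = 4, rp = 0.5, rs = 40) {
  modality <- match.arg(modality)
  band <- switch(modality,
    eb              = list(kind = "bandpass", low = 0.5, high = 5),
    ssvep           = list(kind = "bandpass", low = 2,   high = 54),
    emg             = list(kind = "highpass", low = 0.5, high = NA_real_),
    realtime_common = list(kind = "bandpass", low = 0.5, high = 55))
  hi <- if (is.na(band$high)) band$low else band$high
  if (fs <= 2 * hi) {
    stop("fs = ", fs, " Hz is too low for the ", modality,
         " band (needs fs > ", 2 * hi, " Hz)")
  }
  filt <- if (band$kind == "bandpass") {
    ellip_design(order, rp, rs, c(band$low, band$high), fs, "bandpass")
  } else {
    ellip_design(order, rp, rs, band$low, fs, "highpass")
  }
  structure(list(modality = modality, kind = band$kind,
                 low_hz = band$low, high_hz = band$high,
                 design = "elliptic", order = order,
                 passband_ripple_db = rp, stopband_atten_db = rs,
                 fs = fs, filter = filt),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  edge <- if (x$kind == "bandpass") paste0(x$low_hz, "-", x$high_hz) else paste0(">", x$low_hz)
  cat(sprintf("<filter_spec> %s: elliptic %s %s Hz, order %d, rp %.3g dB, rs %g dB, fs %g Hz\n",
              x$modality, x$kind, edge, x$order, x$passband_ripple_db,
              x$stopband_atten_db, x$fs))
  invisible(x)
}

.sosfilt <- function(sos, x, zi = NULL) {
  if (is.null(zi)) zi <- matrix(0, nrow(sos), 2)
  sosfilt_cpp(sos, as.numeric(x), zi)
}

# zero-phase forward-backward pass with odd edge extension and steady-state
# initial conditions (the standard transient-suppression recipe).
.sosfiltfilt <- function(sos, x) {
  n <- length(x)
  nsec <- nrow(sos)
  # generous padding: low-frequency band edges ring for hundreds of samples
  padlen <- min(n - 1, max(3 * (2 * nsec + 1), 512))
  if (padlen < 1) stop("signal too short to filter (length ", n, ")")
  head_ext <- 2 * x[1] - x[(padlen + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xe <- c(head_ext, x, tail_ext)
  zi <- .sos_zi(sos)
  y <- .sosfilt(sos, xe, zi * xe[1])
  y <- rev(.sosfilt(sos, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Apply a modality filter to a signal
#'
#' Offline analysis uses zero-phase (forward--backward) filtering; the
#' real-time path must be causal, so both modes are explicit.
#'
#' @param x a numeric vector, a channels-by-time matrix, a
#'   \code{bci_recording} or a \code{bci_epoch}.
#' @param spec a \code{filter_spec} from \code{\link{make_filter}} (its
#'   sampling rate must match the data).
#' @param mode \code{"offline_zero_phase"} (default) or \code{"causal"}.
#' @return the filtered object, same class and dimensions as the input.
#' @examples
#' fs <- 512
#' sp <- make_filter("ssvep", fs)
#' t <- seq(0, 2, by = 1 / fs)
#' y <- apply_filter(sin(2 * pi * 9.8 * t) + 10, sp)
#' @export
apply_filter <- function(x, spec, mode = c("offline_zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "filter_spec"))
  one <- function(v) {
    if (length(v) <= 3 * spec$order) {
      stop("signal too short for filtering: length ", length(v))
    }
    if (mode == "offline_zero_phase") .sosfiltfilt(spec$filter$sos, v)
    else .sosfilt(spec$filter$sos, v)
  }
  if (inherits(x, "bci_recording") || inherits(x, "bci_epoch")) {
    if (!isTRUE(all.equal(x$fs, spec$fs))) {
      stop("filter designed for fs = ", spec$fs, " but data are at fs = ", x$fs)
    }
    x$samples <- t(apply(x$samples, 1, one))
    x
  } else if (is.matrix(x)) {
    t(apply(x, 1, one))
  } else {
    one(x)
  }
}
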