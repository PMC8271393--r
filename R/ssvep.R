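# SSVEP recognition by the multivariate synchronization index.
#
# The S-estimator family measures phase-locking between the multichannel
# EEG epoch X (N x M) and sinusoidal references Y (2H x M) at a candidate
# stimulus frequency: build the joint correlation matrix of the stacked
# signals, whiten the two auto-blocks to identity, and summarise the
# eigenvalue spread of the whitened joint matrix by an entropy. Perfect
# synchronization concentrates the spectrum (S -> 1); independence leaves
# it flat (S -> 0). The attended stimulus is the frequency with the
# largest index. No per-subject training is involved.

#' Sinusoidal reference set for one stimulus frequency
#'
#' Rows are \code{sin(2 pi h f t)} and \code{cos(2 pi h f t)} for
#' harmonics \code{h = 1..n_harmonics} on the epoch time grid.
#'
#' @param freq stimulus frequency, Hz.
#' @param n_harmonics harmonic count H.
#' @param n_samples epoch length in samples (M).
#' @param fs sampling rate, Hz.
#' @param strict if \code{TRUE}, a harmonic at or above fs/2 is an error;
#'   otherwise H is reduced with a warning.
#' @return a \code{reference_set}: \code{freq}, \code{n_harmonics},
#'   \code{matrix} (2H x M).
#' @examples
#' r <- make_references(9.8, 2, 2048, 512)
#' dim(r$matrix)  # 4 x 2048
#' @export
make_references <- function(freq, n_harmonics, n_samples, fs, strict = FALSE) {
  if (freq <= 0) stop("freq must be positive")
  H <- n_harmonics
  if (H * freq >= fs / 2) {
    if (strict) stop("harmonic ", H, " of ", freq, " Hz is at/above Nyquist (fs = ", fs, ")")
    H <- max(1, floor((fs / 2 - 1e-9) / freq))
    warning("reduced harmonic count to ", H, " to stay below Nyquist")
  }
  t <- (seq_len(n_samples) - 1) / fs
  Y <- matrix(0, 2 * H, n_samples)
  for (h in seq_len(H)) {
    Y[2 * h - 1, ] <- sin(2 * pi * h * freq * t)
    Y[2 * h, ]     <- cos(2 * pi * h * freq * t)
  }
  structure(list(freq = freq, n_harmonics = H, matrix = Y),
            class = "reference_set")
}

# inverse square root of a symmetric positive semidefinite matrix;
# degenerate directions (relative eigenvalue below tol) are projected out
# rather than floored -- flooring would amplify rounding noise in the null
# space by 1/sqrt(tol) and break exact scale invariance
.inv_sqrt <- function(C, tol = 1e-10) {
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) stop("degenerate block: no usable variance")
  if (!all(keep)) {
    warning("rank-deficient auto-block: whitening restricted to the ",
            sum(keep), "-dimensional non-degenerate subspace")
  }
  V <- e$vectors[, keep, drop = FALSE]
  V %*% diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(V)
}

# center rows; unit-variance rows (correlation convention => scale invariance)
.standardize_rows <- function(X) {
  X <- X - rowMeans(X)
  s <- sqrt(rowMeans(X^2))
  s[s < 1e-300] <- 1
  X / s
}

# one-sample time-delay embedding used by the extended estimator
.delay_embed <- function(X, n_delays) {
  if (n_delays < 1) return(X)
  M <- ncol(X)
  out <- X
  for (d in seq_len(n_delays)) {
    Xd <- cbind(X[, (d + 1):M, drop = FALSE], matrix(0, nrow(X), d))
    out <- rbind(out, Xd)
  }
  out
}

#' Synchronization index between an epoch and a reference set
#'
#' @param epoch N-channel x M-sample numeric matrix (a vector is treated
#'   as one channel), or a \code{bci_epoch}.
#' @param refs a \code{reference_set} with M columns.
#' @param estimator \code{"emsi"} (default): the extended variant, which
#'   time-delay-embeds the EEG block (one-sample delays) before stacking,
#'   capturing a phase lag between stimulus and response; \code{"msi"}:
#'   the plain estimator on the raw channels.
#' @param n_delays delay embedding order for \code{"emsi"} (default 1).
#' @return the synchronization index S in [0, 1].
#' @details Channels are centered and variance-normalised (correlation
#'   convention), so S is invariant to per-channel amplitude scaling.
#'   Rank-deficient auto-blocks (e.g. a constant channel, or noiseless
#'   sinusoids spanning fewer dimensions than channels) trigger a warning
#'   and whitening restricted to the non-degenerate subspace.
#' @export
sync_index <- function(epoch, refs, estimator = c("emsi", "msi"), n_delays = 1) {
  estimator <- match.arg(estimator)
  if (inherits(epoch, "bci_epoch")) epoch <- epoch$samples
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  stopifnot(inherits(refs, "reference_set"))
  Y <- refs$matrix
  if (ncol(epoch) != ncol(Y)) {
    stop("epoch has ", ncol(epoch), " samples but references have ", ncol(Y))
  }
  X <- .standardize_rows(epoch)
  if (estimator == "emsi") X <- .standardize_rows(.delay_embed(X, n_delays))
  Yc <- .standardize_rows(Y)
  N <- nrow(X); M <- ncol(X); Q <- nrow(Yc)
  if (M <= N + Q) stop("epoch too short: need more samples than joint dimension")
  Z <- rbind(X, Yc)
  C <- tcrossprod(Z) / M
  U <- matrix(0, N + Q, N + Q)
  U[1:N, 1:N] <- .inv_sqrt(C[1:N, 1:N, drop = FALSE])
  U[(N + 1):(N + Q), (N + 1):(N + Q)] <- .inv_sqrt(C[(N + 1):(N + Q), (N + 1):(N + Q), drop = FALSE])
  R <- U %*% C %*% t(U)
  R <- (R + t(R)) / 2
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lam <- lam / sum(lam)
  P <- N + Q
  nz <- lam > 0
  S <- 1 + sum(lam[nz] * log(lam[nz])) / log(P)
  min(1, max(0, S))
}

#' Classify the attended stimulus from an occipital epoch
#'
#' Computes the synchronization index against each stimulus frequency and
#' picks the argmax; ties break to the lowest stimulus index.
#'
#' @param epoch occipital channels (1 or 3, re-referenced to Cz and
#'   bandpass filtered) as matrix/vector or \code{bci_epoch}; 3-s or 4-s
#'   epochs are the analysed lengths.
#' @param fs sampling rate, Hz (from the epoch if one is given).
#' @param stimuli a \code{stimulus_set} (default the five flicker
#'   frequencies 7.4, 8.43, 9.8, 11.7, 13.7 Hz).
#' @param n_harmonics reference harmonic count (default 2; the third
#'   harmonic of the highest stimulus would leave the 54-Hz passband).
#' @param estimator passed to \code{\link{sync_index}}.
#' @return a \code{class_decision}: \code{chosen_index} (0-based stimulus
#'   index), \code{chosen_freq_hz}, \code{index_values} (S per stimulus).
#' @examples
#' fs <- 512; t <- (0:2047) / fs
#' ep <- rbind(sin(2 * pi * 9.8 * t), cos(2 * pi * 9.8 * t), sin(2 * pi * 9.8 * t + 1))
#' classify_ssvep(ep, fs)$chosen_index  # 2
#' @export
classify_ssvep <- function(epoch, fs, stimuli = stimulus_set(), n_harmonics = 2,
                           estimator = c("emsi", "msi")) {
  estimator <- match.arg(estimator)
  if (inherits(epoch, "bci_epoch")) {
    fs <- epoch$fs
    epoch <- epoch$samples
  }
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  S <- vapply(stimuli$freqs_hz, function(f) {
    refs <- make_references(f, n_harmonics, ncol(epoch), fs)
    sync_index(epoch, refs, estimator = estimator)
  }, 0)
  names(S) <- sprintf("%g", stimuli$freqs_hz)
  chosen <- as.integer(unname(which.max(S))) - 1L   # first maximum wins ties
  structure(list(chosen_index = chosen,
                 chosen_freq_hz = stimuli$freqs_hz[chosen + 1],
                 index_values = S),
            class = "class_decision")
}

#' @export
print.class_decision <- function(x, ...) {
  cat(sprintf("<class_decision> stimulus %d (%g Hz); S = %s\n",
              x$chosen_index, x$chosen_freq_hz,
              paste(sprintf("%.3f", x$index_values), collapse = ", ")))
  invisible(x)
}
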