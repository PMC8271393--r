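# Fixtures built in code: a tailored single-meal-cycle recording whose
# timing matches the online controller (blink triple at 2-3 s, 9.8-Hz gaze
# from 4-10 s, chew burst from 11-17 s), and small convenience wrappers.

single_cycle_recording <- function(fs = 128, seed = 5, with_chew = TRUE,
                                   dur = 24, ssvep_freq = 9.8) {
  prm <- synthesis_params(fs = fs, seed = seed)
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  set.seed(seed)
  labs <- c("FPz", "T7", "T8", "O1", "Oz", "O2", "Cz")
  X <- matrix(0, length(labs), n, dimnames = list(labs, NULL))
  for (l in labs) {
    ns <- synth_blink_train(0, 0, synthesis_params(fs = fs, seed = seed + match(l, labs)),
                            dur)$signal
    X[l, ] <- ns
  }
  blink <- synth_blink_train(3, 0.5, synthesis_params(fs = fs, noise_rms_uv = 0,
                                                      seed = seed), dur,
                             start_s = 2)
  X["FPz", ] <- X["FPz", ] + blink$signal
  sel <- t >= 4 & t < 10
  sig <- 15 * sin(2 * pi * ssvep_freq * t[sel])
  for (ch in c("O1", "Oz", "O2")) X[ch, sel] <- X[ch, sel] + sig
  if (with_chew) {
    selb <- t >= 11 & t < 17
    m <- sum(selb)
    for (ch in c("T7", "T8")) {
      b <- stats::rnorm(m)
      B <- stats::fft(b)
      f <- (seq_len(m) - 1) * fs / m
      f2 <- pmin(f, fs - f)
      b <- Re(stats::fft(B * (f2 >= 15 & f2 <= 55), inverse = TRUE)) / m
      X[ch, selb] <- X[ch, selb] + b * 40 / stats::sd(b)
    }
  }
  recording(X, fs, labs)
}

# command subsequence (kinds only, in onset order) from a session log
command_kinds <- function(log) {
  cmds <- log[grepl("^cmd:", log$label), , drop = FALSE]
  sub("^cmd:", "", cmds$label[order(cmds$onset_s)])
}
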