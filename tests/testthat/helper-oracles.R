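# Independent oracles, kept deliberately naive: direct transcriptions of the
# defining formulas, no shared code with the implementation under test.

# Kraskov-Stoegbauer-Grassberger algorithm-1 MI, naive O(n^2) scans.
ksg_brute <- function(x, y, k = 4L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  maxnorm <- function(m, i, j) max(abs(m[i, ] - m[j, ]))
  s <- 0
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      max(maxnorm(x, i, j), maxnorm(y, i, j))
    })
    eps <- sort(d)[k]
    nx <- sum(sapply(seq_len(n), function(j) j != i && maxnorm(x, i, j) < eps))
    ny <- sum(sapply(seq_len(n), function(j) j != i && maxnorm(y, i, j) < eps))
    s <- s + digamma(nx + 1) + digamma(ny + 1)
  }
  digamma(k) + digamma(n) - s / n
}

# Jammalamadaka-SenGupta circular correlation, textbook transcription.
ccor_textbook <- function(theta, phi) {
  tbar <- Arg(sum(exp(1i * theta)))
  pbar <- Arg(sum(exp(1i * phi)))
  num <- sum(sin(theta - tbar) * sin(phi - pbar))
  den <- sqrt(sum(sin(theta - tbar)^2) * sum(sin(phi - pbar)^2))
  num / den
}

# Small, fast scenario used across tests: two task phases + cooperation,
# no eyes-closed block (tests that need IAF estimation build their own).
quick_scenario <- function(seed = 1L, coupling = 0.8, shared = 0,
                           phase_s = 30, noise = 2, blink_rate = 0, ...) {
  dyad_scenario(
    phases = data.frame(label = c("low_diff", "high_diff", "cooperation"),
                        duration_s = rep(phase_s, 3)),
    phase_coupling = coupling, shared_state_corr = shared,
    noise_rms_uV = noise, blink_rate = blink_rate, seed = seed, ...)
}

# Sinusoid-built epoched object: one channel set with known amplitudes.
# amps: named list channel -> function(t) amplitude (constant ok), freq: Hz.
make_epochs <- function(channels, freqs, amps, n_epochs = 20, fs = 125) {
  n <- n_epochs * fs
  t <- (seq_len(n) - 1) / fs
  m <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
  for (i in seq_along(channels)) {
    m[i, ] <- amps[[i]] * cos(2 * pi * freqs[[i]] * t)
  }
  rec <- eeg_recording(m, fs, channels)
  epoch_and_mask(rec, 1, amp_threshold_uV = 1e6)
}
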