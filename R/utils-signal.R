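#' Analytic signal via the frequency domain
#'
#' Computes the analytic signal `x + i * H(x)` of a real vector, where `H` is
#' the Hilbert transform, by zeroing negative frequencies in the DFT. The
#' instantaneous phase of a band-limited signal is the complex argument of its
#' analytic signal.
#'
#' @param x numeric vector, a real-valued signal.
#' @return complex vector of the same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 125)
#' ph <- Arg(analytic_signal(cos(2 * pi * 10 * t)))
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) > 1L)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-pass filter a signal with a zero-phase Butterworth filter
#'
#' Forward-backward (zero-phase) application so that downstream phase
#' estimates do not inherit the filter's group delay.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `lo = 0` gives a low-pass filter.
#' @param order filter order (of the underlying one-directional design).
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
butter_bandpass <- function(x, fs, lo, hi, order = 4L) {
  nyq <- fs / 2
  stopifnot(hi < nyq, lo < hi, lo >= 0)
  flt <- if (lo <= 0) {
    signal::butter(order, hi / nyq, type = "low")
  } else {
    signal::butter(order, c(lo, hi) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(flt, x))
}
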