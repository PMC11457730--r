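#' Instantaneous region phase of a recording
#'
#' Per channel, the signal is (optionally) band-pass filtered to the target
#' band and its instantaneous phase taken as the complex argument of the
#' analytic signal. The region phase is the angle of the mean unit phasor
#' across the channel set, which reduces exactly to the single-channel phase
#' when one channel is named (or when all named channels carry the same
#' signal).
#'
#' @param rec an [eeg_recording], normally already preprocessed to 2-30 Hz.
#' @param channels channel labels to aggregate.
#' @param band numeric `c(lo, hi)` in Hz to refilter to before phase
#'   extraction, or NULL (default) to take the signal's existing band. The
#'   band must lie inside the preprocessed range.
#' @param preprocessed_range the band the recording already occupies (default
#'   `c(2, 30)`); a requested `band` wider than this is an error.
#' @return an object of class `phase_series`: list with `phases` (radians per
#'   sample, in `(-pi, pi]`), `fs`, `channels`, `band`.
#' @export
instantaneous_phase <- function(rec, channels, band = NULL,
                                preprocessed_range = c(2, 30)) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing)) stop("channel(s) not present: ", paste(missing, collapse = ", "))
  if (!is.null(band)) {
    stopifnot(length(band) == 2L, band[1] < band[2])
    if (band[1] < preprocessed_range[1] - 1e-9 ||
        band[2] > preprocessed_range[2] + 1e-9) {
      stop("requested band [", band[1], ", ", band[2],
           "] Hz wider than the preprocessed range [",
           preprocessed_range[1], ", ", preprocessed_range[2], "] Hz")
    }
  }
  z <- 0
  for (ch in channels) {
    x <- rec$samples[ch, ]
    if (!is.null(band)) x <- butter_bandpass(x, rec$fs, band[1], band[2], order = 4L)
    z <- z + exp(1i * Arg(analytic_signal(x)))
  }
  structure(list(phases = wrap_phase(Arg(z)), fs = rec$fs,
                 channels = channels,
                 band = if (is.null(band)) preprocessed_range else band),
            class = "phase_series")
}

# Sample-level validity from an epoch-level artifact mask.
.sample_valid <- function(mask, spe, n_samples) {
  v <- rep(rep(!mask, each = spe), length.out = n_samples)
  if (length(v) < n_samples) v <- c(v, rep(FALSE, n_samples - length(v)))
  v
}

#' Circular-correlation cooperation index (CCI) over time
#'
#' For each sliding window, computes the circular correlation between the two
#' operators' instantaneous region phases. The index is computed on the full
#' preprocessed band (2-30 Hz) and, optionally, on individual
#' IAF-anchored bands; and separately for the frontal (AF3, AFz, AF4) and
#' parietal (P3, Pz, P4) regions.
#'
#' The two recordings are aligned on their session start (sample 1 to sample
#' 1); for surrogate pairings of unequal length the pair is truncated to the
#' shorter recording. Samples falling in artifactual epochs of either
#' operator are dropped pairwise inside each window; windows retaining fewer
#' than `min_valid_frac` of their samples are invalid, as are windows whose
#' circular correlation is undefined (phase-constant input).
#'
#' @param session a [crew_session] of preprocessed recordings.
#' @param channels channel set defining the region (default frontal:
#'   AF3, AFz, AF4).
#' @param band `c(lo, hi)` in Hz, or NULL for the full preprocessed band.
#' @param window_s,step_s sliding-window length and step in seconds
#'   (default 30/30, the behavioural rating cadence).
#' @param artifact_masks optional list of two logical epoch masks (TRUE =
#'   artifactual), one per operator, with `epoch_length_s` attribute-free 1-s
#'   epochs assumed.
#' @param epoch_length_s epoch length the masks refer to (default 1).
#' @param min_valid_frac minimum fraction of pairwise-valid samples a window
#'   needs (default 0.5).
#' @param region label stored on the output series (default from channels).
#' @return a [feature_series] of kind `"CCI"`.
#' @export
cci_series <- function(session, channels = .frontal_channels, band = NULL,
                       window_s = 30, step_s = 30, artifact_masks = NULL,
                       epoch_length_s = 1, min_valid_frac = 0.5,
                       region = NULL) {
  stopifnot(inherits(session, "crew_session"))
  if (window_s < 2) stop("window_s must be >= 2 s")
  r1 <- session$rec1
  r2 <- session$rec2
  if (r1$fs != r2$fs) stop("operators recorded at different sampling rates")
  n <- min(ncol(r1$samples), ncol(r2$samples))
  fs <- r1$fs

  p1 <- instantaneous_phase(r1, channels, band)$phases[seq_len(n)]
  p2 <- instantaneous_phase(r2, channels, band)$phases[seq_len(n)]

  spe <- round(epoch_length_s * fs)
  valid <- rep(TRUE, n)
  if (!is.null(artifact_masks)) {
    stopifnot(length(artifact_masks) == 2L)
    valid <- .sample_valid(artifact_masks[[1L]], spe, n) &
      .sample_valid(artifact_masks[[2L]], spe, n)
  }

  wlen <- round(window_s * fs)
  step <- round(step_s * fs)
  starts <- seq(1L, n - wlen + 1L, by = step)
  if (length(starts) == 0L) stop("recordings shorter than one window")
  vals <- rep(NA_real_, length(starts))
  ok <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + wlen - 1L)
    use <- idx[valid[idx]]
    if (length(use) < min_valid_frac * wlen) next
    cc <- circular_correlation(p1[use], p2[use])
    if (!is.na(cc)) {
      vals[i] <- cc
      ok[i] <- TRUE
    }
  }
  if (is.null(region)) {
    region <- if (setequal(channels, .frontal_channels)) "frontal"
      else if (setequal(channels, .parietal_channels)) "parietal"
      else paste(channels, collapse = "+")
  }
  band_label <- if (is.null(band)) "full" else paste0(band[1], "-", band[2], "Hz")
  feature_series(vals, window_s, (starts - 1L) / fs, kind = "CCI",
                 operator_id = paste(r1$operator_id, r2$operator_id, sep = "+"),
                 band = band_label, valid_mask = ok, region = region)
}
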