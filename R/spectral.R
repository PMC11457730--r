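#' Individual-alpha-frequency anchored band scheme
#'
#' Frequency bands are anchored to each operator's individual alpha frequency
#' (IAF): theta = [IAF - 6, IAF - 2], alpha = [IAF - 2, IAF + 2],
#' beta = [IAF + 2, IAF + 16] Hz. The bands are contiguous and ordered.
#'
#' @param iaf individual alpha frequency in Hz; must lie in [7, 13].
#' @return an object of class `band_scheme` with elements `theta`, `alpha`,
#'   `beta` (each `c(lo, hi)` in Hz) and `iaf`.
#' @examples
#' bands_from_iaf(10) # theta 4-8, alpha 8-12, beta 12-26
#' @export
bands_from_iaf <- function(iaf) {
  if (!is.numeric(iaf) || length(iaf) != 1L || iaf < 7 || iaf > 13) {
    stop("IAF must be a single value in [7, 13] Hz, got ", iaf)
  }
  structure(list(theta = c(iaf - 6, iaf - 2),
                 alpha = c(iaf - 2, iaf + 2),
                 beta  = c(iaf + 2, iaf + 16),
                 iaf = iaf),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> IAF = %g Hz: theta [%g, %g], alpha [%g, %g], beta [%g, %g] Hz\n",
              x$iaf, x$theta[1], x$theta[2], x$alpha[1], x$alpha[2],
              x$beta[1], x$beta[2]))
  invisible(x)
}

# Segment-averaged (Welch) periodogram, Hann window, 50% overlap.
# Returns data.frame(freq, power). Resolution fs/nfft.
.welch_psd <- function(x, fs, seg_len = 512L) {
  seg_len <- min(seg_len, length(x))
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / length(starts)
  half <- seq_len(seg_len %/% 2L + 1L)
  data.frame(freq = (half - 1L) * fs / seg_len, power = p[half])
}

#' Estimate the individual alpha frequency from an eyes-closed recording
#'
#' Averages the Welch power spectra of the parietal channels (P3, Pz, P4 by
#' default) and returns the frequency of the maximum within the 7-13 Hz search
#' range. If the maximum sits at the edge of the search range there is no
#' genuine local alpha peak (typical of pure 1/f spectra); the function then
#' falls back to 10 Hz with a warning.
#'
#' @param rec eyes-closed [eeg_recording]; at least 30 s long.
#' @param channels parietal channels to average (default P3, Pz, P4;
#'   whichever of them are present).
#' @param search numeric `c(lo, hi)` search range in Hz (default `c(7, 13)`).
#' @return IAF estimate in Hz.
#' @export
estimate_iaf <- function(rec, channels = .parietal_channels, search = c(7, 13)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (recording_duration(rec) < 30) {
    stop("eyes-closed recording too short (< 30 s) for IAF estimation")
  }
  channels <- intersect(channels, rec$channel_labels)
  if (length(channels) == 0L) stop("no parietal channels present for IAF estimation")
  psds <- lapply(channels, function(ch) .welch_psd(rec$samples[ch, ], rec$fs))
  freq <- psds[[1]]$freq
  pow <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  in_range <- which(freq >= search[1] & freq <= search[2])
  imax <- in_range[which.max(pow[in_range])]
  at_edge <- imax == in_range[1L] || imax == in_range[length(in_range)]
  if (at_edge) {
    warning("no local alpha peak in [", search[1], ", ", search[2],
            "] Hz; falling back to IAF = 10 Hz")
    return(10)
  }
  freq[imax]
}

#' Global field power of a band over a channel set
#'
#' Operationalised as mean band power: per epoch, the band-pass-filtered
#' signal is squared and averaged over time and over the named channels; per
#' window, powers are averaged over the non-artifact epochs. With a single
#' channel this reduces to that channel's band power, which is the reading
#' the single-channel asymmetry feature requires. A window whose artifactual
#' fraction exceeds `max_artifact_frac` is marked invalid.
#'
#' Filtering runs on the concatenated (contiguous) epochs so epoch edges add
#' no transient; a 4th-order zero-phase Butterworth is used for band
#' selection.
#'
#' @param ep an [epoched_eeg].
#' @param band numeric `c(lo, hi)` band in Hz.
#' @param channels channel labels to include.
#' @param window_s window length in seconds; must be a multiple of the epoch
#'   length (default: one epoch).
#' @param max_artifact_frac invalidate windows with more than this fraction of
#'   artifactual epochs (default 0.5).
#' @return a [feature_series] of kind `"GFP"` in microvolts squared.
#' @export
gfp <- function(ep, band, channels, window_s = ep$epoch_length_s,
                max_artifact_frac = 0.5) {
  stopifnot(inherits(ep, "epoched_eeg"), length(band) == 2L, band[1] < band[2])
  missing <- setdiff(channels, ep$channel_labels)
  if (length(missing)) stop("channel(s) not present: ", paste(missing, collapse = ", "))
  per_win <- window_s / ep$epoch_length_s
  if (abs(per_win - round(per_win)) > 1e-9) {
    stop("window_s must be a multiple of the epoch length")
  }
  per_win <- as.integer(round(per_win))
  n_ep <- dim(ep$epochs)[1L]
  spe <- dim(ep$epochs)[3L]
  idx <- match(channels, ep$channel_labels)

  # epoch x channel matrix of band power
  pow <- matrix(NA_real_, n_ep, length(idx))
  for (j in seq_along(idx)) {
    cont <- as.vector(t(ep$epochs[, idx[j], ])) # concatenated samples
    filt <- butter_bandpass(cont, ep$fs, band[1], band[2], order = 4L)
    pow[, j] <- colMeans(matrix(filt^2, nrow = spe))
  }
  ep_pow <- rowMeans(pow)

  n_win <- floor(n_ep / per_win)
  if (n_win < 1L) stop("fewer epochs than one window")
  vals <- rep(NA_real_, n_win)
  ok <- logical(n_win)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * per_win + 1L):(w * per_win)
    good <- !ep$artifact_mask[rows]
    if (mean(!good) > max_artifact_frac || !any(good)) next
    vals[w] <- mean(ep_pow[rows][good])
    ok[w] <- TRUE
  }
  if (!any(ok)) stop("no valid epochs anywhere in the series")
  feature_series(vals, window_s,
                 start_times = (seq_len(n_win) - 1L) * window_s, kind = "GFP",
                 operator_id = ep$operator_id, valid_mask = ok)
}

#' Mental workload index W(t)
#'
#' The ratio of frontal theta power to parietal alpha power:
#' `W(t) = GFP_theta(AF3, AFz, AF4) / GFP_alpha(P3, Pz, P4)`. Higher values
#' indicate more cognitive effort. A window is invalid when either factor is
#' invalid or the denominator falls below `floor_uV2` (the window is dropped,
#' not clipped).
#'
#' @param ep an [epoched_eeg] with the six required channels.
#' @param scheme a [band_scheme].
#' @param window_s window length in seconds (default one epoch).
#' @param floor_uV2 denominator floor in microvolts squared (default 1e-12).
#' @return a [feature_series] of kind `"W"` (dimensionless).
#' @export
workload_index <- function(ep, scheme, window_s = ep$epoch_length_s,
                           floor_uV2 = 1e-12) {
  stopifnot(inherits(scheme, "band_scheme"))
  need <- c(.frontal_channels, .parietal_channels)
  missing <- setdiff(need, ep$channel_labels)
  if (length(missing)) stop("workload index needs channel(s): ",
                            paste(missing, collapse = ", "))
  num <- gfp(ep, scheme$theta, .frontal_channels, window_s)
  den <- gfp(ep, scheme$alpha, .parietal_channels, window_s)
  ok <- num$valid_mask & den$valid_mask & !is.na(den$values) &
    den$values > floor_uV2
  vals <- ifelse(ok, num$values / den$values, NA_real_)
  feature_series(vals, window_s, num$start_times, kind = "W",
                 operator_id = ep$operator_id, valid_mask = ok)
}

#' Approach-withdrawal index AW(t)
#'
#' Frontal alpha-power asymmetry: `AW(t) = GFP_alpha(AF4) - GFP_alpha(AF3)`.
#' Positive values index approach motivation (relatively less right-frontal
#' alpha would reverse the sign; the AF4-minus-AF3 convention is fixed).
#'
#' @param ep an [epoched_eeg] with AF3 and AF4.
#' @param scheme a [band_scheme].
#' @param window_s window length in seconds (default one epoch).
#' @return a [feature_series] of kind `"AW"` in microvolts squared.
#' @export
approach_withdrawal_index <- function(ep, scheme, window_s = ep$epoch_length_s) {
  stopifnot(inherits(scheme, "band_scheme"))
  missing <- setdiff(c("AF3", "AF4"), ep$channel_labels)
  if (length(missing)) stop("approach-withdrawal index needs channel(s): ",
                            paste(missing, collapse = ", "))
  a4 <- gfp(ep, scheme$alpha, "AF4", window_s)
  a3 <- gfp(ep, scheme$alpha, "AF3", window_s)
  ok <- a4$valid_mask & a3$valid_mask
  vals <- ifelse(ok, a4$values - a3$values, NA_real_)
  feature_series(vals, window_s, a4$start_times, kind = "AW",
                 operator_id = ep$operator_id, valid_mask = ok)
}
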