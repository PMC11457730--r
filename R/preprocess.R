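#' Band-pass + notch filter specification
#'
#' Defaults follow the wearable-EEG processing chain the package implements:
#' 2-30 Hz 5th-order Butterworth band-pass with a 50 Hz mains notch, applied
#' forward-backward (zero phase) so phase metrics downstream do not inherit
#' group delay.
#'
#' @param highpass_hz high-pass cutoff (default 2).
#' @param lowpass_hz low-pass cutoff (default 30).
#' @param order Butterworth order (default 5).
#' @param notch_hz mains notch frequency, or NA to skip (default 50).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 2, lowpass_hz = 30, order = 5L,
                        notch_hz = 50, zero_phase = TRUE) {
  stopifnot(highpass_hz > 0, highpass_hz < lowpass_hz, order >= 1)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 order = as.integer(order), notch_hz = notch_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Channels required by the downstream feature formulas.
.required_channels <- c("AF3", "AF4", "AFz", "P3", "P4", "Pz")
.frontal_channels <- c("AF3", "AFz", "AF4")
.parietal_channels <- c("P3", "Pz", "P4")
.default_channels <- c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4")

#' Read an EEG recording from CSV/TSV
#'
#' Two layouts are supported: `"wide"` (a time column named `time_s` plus one
#' column per channel, values in microvolts) and `"long"` (columns `time_s`,
#' `channel`, `value_uV`). The sampling rate is inferred from the time column
#' and checked for uniformity.
#'
#' @param path file path.
#' @param format `"wide"` or `"long"`; default guesses from the header.
#' @param channels channels that must be present; error if any is missing
#'   (NULL = accept whatever the file holds).
#' @param phase_annotations,operator_id,session_id metadata to attach.
#' @param sep field separator (default `,`; use `"\t"` for TSV).
#' @return an [eeg_recording].
#' @export
read_recording_csv <- function(path, format = c("auto", "wide", "long"),
                               channels = NULL, phase_annotations = NULL,
                               operator_id = "op", session_id = "session",
                               sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("unreadable recording: no 'time_s' column in ", path)
  if (format == "auto") {
    format <- if (all(c("channel", "value_uV") %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    if (!all(c("channel", "value_uV") %in% names(df))) {
      stop("long format needs columns time_s, channel, value_uV")
    }
    labs <- unique(df$channel)
    times <- sort(unique(df$time_s))
    m <- matrix(NA_real_, length(labs), length(times), dimnames = list(labs, NULL))
    for (ch in labs) {
      sub <- df[df$channel == ch, ]
      sub <- sub[order(sub$time_s), ]
      if (nrow(sub) != length(times)) stop("long CSV not rectangular for channel ", ch)
      m[ch, ] <- sub$value_uV
    }
    samples <- m
  } else {
    labs <- setdiff(names(df), "time_s")
    times <- df$time_s
    samples <- t(as.matrix(df[, labs, drop = FALSE]))
  }
  dt <- diff(times)
  if (length(dt) < 1L || diff(range(dt)) > 1e-6) {
    stop("inconsistent sampling: time column is not uniformly spaced")
  }
  fs <- 1 / stats::median(dt)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labs)
    if (length(missing)) {
      stop("required channel(s) missing from ", path, ": ",
           paste(missing, collapse = ", "))
    }
  }
  eeg_recording(samples, fs = fs, channel_labels = labs,
                phase_annotations = phase_annotations,
                operator_id = operator_id, session_id = session_id)
}

#' Write an EEG recording to CSV
#'
#' @param rec an [eeg_recording].
#' @param path destination file.
#' @param format `"wide"` (default) or `"long"` layout (see
#'   [read_recording_csv()]).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, format = c("wide", "long")) {
  format <- match.arg(format)
  t_s <- seq(0, by = 1 / rec$fs, length.out = ncol(rec$samples))
  if (format == "wide") {
    df <- data.frame(time_s = t_s, t(rec$samples), check.names = FALSE)
  } else {
    df <- data.frame(
      time_s = rep(t_s, each = nrow(rec$samples)),
      channel = rep(rec$channel_labels, times = ncol(rec$samples)),
      value_uV = as.vector(rec$samples))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Drop channels from a recording
#'
#' Movement-artifact-prone channels (in the reference montage, AF7 and AF8)
#' are removed before analysis. Excluding a channel that a downstream feature
#' formula requires (AF3, AF4, AFz, P3, P4, Pz) is a configuration error when
#' `check_required = TRUE`.
#'
#' @param rec an [eeg_recording].
#' @param labels channels to drop (must be a subset of the recording's).
#' @param check_required error if a required channel would be dropped
#'   (default FALSE; pipeline assembly sets TRUE).
#' @return the recording without the named channels, order preserved.
#' @export
exclude_channels <- function(rec, labels, check_required = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(labels) == 0L) return(rec)
  unknown <- setdiff(labels, rec$channel_labels)
  if (length(unknown)) stop("cannot exclude unknown channel(s): ",
                            paste(unknown, collapse = ", "))
  if (check_required) {
    clash <- intersect(labels, .required_channels)
    if (length(clash)) {
      stop("configuration error: channel(s) required by the feature formulas ",
           "would be excluded: ", paste(clash, collapse = ", "))
    }
  }
  keep <- !(rec$channel_labels %in% labels)
  eeg_recording(rec$samples[keep, , drop = FALSE], rec$fs,
                rec$channel_labels[keep], rec$phase_annotations,
                rec$operator_id, rec$session_id)
}

#' Band-pass and notch filter a recording (zero phase)
#'
#' Applies the notch (a 2nd-order Butterworth band-stop of +-1 Hz around
#' `notch_hz`, skipped when the band lies above Nyquist or `notch_hz` is NA)
#' followed by the Butterworth band-pass, each channel independently and
#' forward-backward, so the output has no group delay and no DC component.
#'
#' @param rec an [eeg_recording].
#' @param spec a [filter_spec].
#' @return the filtered recording.
#' @export
bandpass_notch <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$lowpass_hz >= nyq) {
    stop("low-pass cutoff ", spec$lowpass_hz, " Hz >= Nyquist (", nyq, " Hz)")
  }
  apply_filt <- function(flt, x) {
    if (spec$zero_phase) as.numeric(signal::filtfilt(flt, x))
    else as.numeric(signal::filter(flt, x))
  }
  out <- rec$samples
  if (!is.na(spec$notch_hz) && spec$notch_hz + 1 < nyq) {
    stopf <- signal::butter(2, c(spec$notch_hz - 1, spec$notch_hz + 1) / nyq,
                            type = "stop")
    for (i in seq_len(nrow(out))) out[i, ] <- apply_filt(stopf, out[i, ])
  }
  bp <- signal::butter(spec$order,
                       c(spec$highpass_hz, spec$lowpass_hz) / nyq,
                       type = "pass")
  for (i in seq_len(nrow(out))) out[i, ] <- apply_filt(bp, out[i, ])
  eeg_recording(out, rec$fs, rec$channel_labels, rec$phase_annotations,
                rec$operator_id, rec$session_id)
}

#' Segment a recording into fixed epochs and mask artifactual ones
#'
#' Cuts the recording into contiguous, non-overlapping epochs (default 1 s;
#' any trailing partial epoch is dropped) and flags an epoch artifactual when
#' the amplitude of any retained channel exceeds the threshold, the standard
#' +-80 microvolt rule. Because the check runs on retained channels only,
#' artifacts on previously excluded channels cannot mask epochs.
#'
#' @param rec an [eeg_recording] (normally already filtered).
#' @param epoch_length_s epoch length in seconds (default 1).
#' @param amp_threshold_uV absolute amplitude threshold in microvolts
#'   (default 80).
#' @param rule `"any"` (default): an epoch is artifactual if any retained
#'   channel exceeds the threshold; `"per_channel"` additionally stores the
#'   per-channel exceedance matrix in attribute `"channel_mask"`.
#' @return an [epoched_eeg] with the artifact mask.
#' @export
epoch_and_mask <- function(rec, epoch_length_s = 1, amp_threshold_uV = 80,
                           rule = c("any", "per_channel")) {
  stopifnot(inherits(rec, "eeg_recording"))
  rule <- match.arg(rule)
  if (epoch_length_s <= 0) stop("epoch length must be positive")
  spe <- round(epoch_length_s * rec$fs) # samples per epoch
  n <- ncol(rec$samples)
  n_ep <- floor(n / spe)
  if (n_ep < 1L) stop("recording shorter than one epoch")
  nch <- nrow(rec$samples)
  ep <- array(NA_real_, dim = c(n_ep, nch, spe))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- rec$samples[, ((e - 1L) * spe + 1L):(e * spe), drop = FALSE]
  }
  ch_exceed <- apply(abs(ep) > amp_threshold_uV, c(1, 2), any)
  mask <- apply(ch_exceed, 1, any)
  out <- epoched_eeg(ep, epoch_length_s, mask, rec$fs, rec$channel_labels,
                     rec$phase_annotations, rec$operator_id, rec$session_id)
  if (rule == "per_channel") attr(out, "channel_mask") <- ch_exceed
  out
}

#' Preprocess a raw recording end to end
#'
#' Convenience chain: optional channel exclusion (with the required-channel
#' check), an optional pluggable ocular-correction hook (default: none; the
#' amplitude threshold is the safety net), zero-phase notch + band-pass
#' filtering, then epoching with the +-80 microvolt artifact rule.
#'
#' @param rec raw [eeg_recording].
#' @param exclude channels to drop first (default AF7, AF8).
#' @param spec a [filter_spec].
#' @param epoch_length_s,amp_threshold_uV see [epoch_and_mask()].
#' @param ocular_hook optional `function(rec) rec` applied after filtering,
#'   before epoching (slot for a blink-correction method).
#' @return an [epoched_eeg].
#' @export
preprocess_recording <- function(rec, exclude = c("AF7", "AF8"),
                                 spec = filter_spec(), epoch_length_s = 1,
                                 amp_threshold_uV = 80, ocular_hook = NULL) {
  exclude <- intersect(exclude, rec$channel_labels)
  rec <- exclude_channels(rec, exclude, check_required = TRUE)
  rec <- bandpass_notch(rec, spec)
  if (!is.null(ocular_hook)) rec <- ocular_hook(rec)
  epoch_and_mask(rec, epoch_length_s, amp_threshold_uV)
}
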