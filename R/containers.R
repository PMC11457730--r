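#' Run code with a temporary RNG seed, restoring global RNG state
#'
#' All randomness in the package flows through this helper so that simulation
#' and permutation results are reproducible from an explicit seed without
#' clobbering the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Multichannel EEG recording
#'
#' The raw substrate of the pipeline: a channels-by-time matrix in microvolts
#' with a sampling rate, ordered channel labels, and session metadata
#' including phase annotations (e.g. eyes-closed, low-difficulty calibration,
#' high-difficulty calibration, cooperation).
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row.
#' @param phase_annotations data.frame with columns `label`, `start_s`,
#'   `end_s`, or NULL.
#' @param operator_id,session_id identifiers carried through the pipeline.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels,
                          phase_annotations = NULL,
                          operator_id = "op", session_id = "session") {
  samples <- as.matrix(samples)
  if (anyNA(samples)) stop("recording contains NA samples")
  if (length(channel_labels) != nrow(samples)) {
    stop("channel_labels length must equal number of rows of samples")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  stopifnot(is.numeric(fs), fs > 0)
  dur <- ncol(samples) / fs
  if (!is.null(phase_annotations)) {
    stopifnot(all(c("label", "start_s", "end_s") %in% names(phase_annotations)))
    if (any(phase_annotations$start_s < 0) ||
        any(phase_annotations$end_s > dur + 1e-9)) {
      stop("phase annotations fall outside the recording [0, ", dur, "] s")
    }
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 phase_annotations = phase_annotations,
                 operator_id = operator_id, session_id = session_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %.1f s @ %g Hz\n",
              x$session_id, x$operator_id, nrow(x$samples),
              ncol(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$phase_annotations)) {
    cat("  phases:  ", paste(sprintf("%s [%g-%g s]", x$phase_annotations$label,
                                     x$phase_annotations$start_s,
                                     x$phase_annotations$end_s),
                             collapse = "; "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [eeg_recording].
#' @return seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Epoched EEG with artifact mask
#'
#' @param epochs 3-d array, epoch x channel x sample, microvolts.
#' @param epoch_length_s epoch length in seconds.
#' @param artifact_mask logical, one flag per epoch (TRUE = artifactual).
#' @param fs sampling rate in Hz.
#' @param channel_labels channel labels matching dim 2.
#' @param phase_annotations,operator_id,session_id metadata carried over.
#' @return an object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(epochs, epoch_length_s, artifact_mask, fs,
                        channel_labels, phase_annotations = NULL,
                        operator_id = "op", session_id = "session") {
  stopifnot(length(dim(epochs)) == 3L,
            length(artifact_mask) == dim(epochs)[1L],
            length(channel_labels) == dim(epochs)[2L])
  structure(list(epochs = epochs, epoch_length_s = epoch_length_s,
                 artifact_mask = as.logical(artifact_mask), fs = fs,
                 channel_labels = as.character(channel_labels),
                 phase_annotations = phase_annotations,
                 operator_id = operator_id, session_id = session_id),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("<epoched_eeg> %s/%s: %d epochs of %g s, %d channels, %d artifactual\n",
              x$session_id, x$operator_id, dim(x$epochs)[1L], x$epoch_length_s,
              dim(x$epochs)[2L], sum(x$artifact_mask)))
  invisible(x)
}

#' Windowed scalar feature series
#'
#' Container for the time courses the pipeline produces: W(t), AW(t), CCI(t),
#' MICI(t). Each window carries a validity flag; windows dominated by
#' artifactual epochs (or with undefined statistics) are invalid rather than
#' zero.
#'
#' @param values numeric, one value per window (NA allowed where invalid).
#' @param window_s window length in seconds.
#' @param start_times numeric, window start times in seconds.
#' @param kind one of "W", "AW", "CCI", "MICI", "GFP".
#' @param operator_id operator(s) the series belongs to.
#' @param band band label ("theta", "alpha", "beta", "full") where applicable.
#' @param valid_mask logical per window; defaults to `!is.na(values)`.
#' @param region optional region label ("frontal", "parietal").
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(values, window_s, start_times, kind,
                           operator_id = "op", band = NA_character_,
                           valid_mask = NULL, region = NA_character_) {
  kind <- match.arg(kind, c("W", "AW", "CCI", "MICI", "GFP"))
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  stopifnot(length(values) == length(start_times),
            length(values) == length(valid_mask))
  if (any(valid_mask & !is.finite(values))) {
    stop("non-finite values in windows marked valid")
  }
  structure(list(values = as.numeric(values), window_s = window_s,
                 start_times = as.numeric(start_times), kind = kind,
                 operator_id = operator_id, band = band,
                 valid_mask = as.logical(valid_mask), region = region),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<feature_series> %s (%s%s), %d windows of %g s, %d valid\n",
              x$kind, x$operator_id,
              if (!is.na(x$band)) paste0(", ", x$band) else "",
              length(x$values), x$window_s, sum(x$valid_mask)))
  if (length(v)) {
    cat(sprintf("  median %.4g  [min %.4g, max %.4g]\n",
                stats::median(v), min(v), max(v)))
  }
  invisible(x)
}

#' @export
as.data.frame.feature_series <- function(x, ...) {
  data.frame(window_start_s = x$start_times, kind = x$kind, band = x$band,
             operator = x$operator_id, value = x$values, valid = x$valid_mask,
             stringsAsFactors = FALSE)
}

#' Mean of the valid windows of a feature series
#' @param x a [feature_series].
#' @param ... unused.
#' @return scalar mean over valid windows (NA if none).
#' @export
mean.feature_series <- function(x, ...) {
  if (!any(x$valid_mask)) return(NA_real_)
  mean(x$values[x$valid_mask])
}

#' Restrict a feature series to windows inside given phases
#'
#' @param x a [feature_series].
#' @param phase_annotations data.frame with `label`, `start_s`, `end_s`.
#' @param phases character vector of phase labels to keep.
#' @return a [feature_series] containing only windows that start inside one of
#'   the named phases.
#' @export
filter_phase <- function(x, phase_annotations, phases) {
  stopifnot(inherits(x, "feature_series"))
  ann <- phase_annotations[phase_annotations$label %in% phases, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotations match phases: ",
                            paste(phases, collapse = ", "))
  keep <- rep(FALSE, length(x$start_times))
  for (i in seq_len(nrow(ann))) {
    keep <- keep | (x$start_times >= ann$start_s[i] - 1e-9 &
                    x$start_times + x$window_s <= ann$end_s[i] + 1e-9)
  }
  feature_series(x$values[keep], x$window_s, x$start_times[keep], x$kind,
                 x$operator_id, x$band, x$valid_mask[keep], x$region)
}

#' Two-operator crew session
#'
#' A pair of time-aligned recordings (REAL crews) or a surrogate pairing from
#' different sessions/phases (FAKE crews), with shared phase annotations and
#' an optional behavioural rating series (one score per rating window).
#'
#' @param rec1,rec2 [eeg_recording] objects for the two operators.
#' @param crew_id identifier.
#' @param crew_type `"REAL"` or `"FAKE"`.
#' @param experience optional `"EXP"` or `"UNEXP"` label.
#' @param ratings optional data.frame of behavioural ratings with columns
#'   `window_start_s` and one rating column per operator (crew-level score =
#'   mean of the two).
#' @param provenance for FAKE crews, a record of the source sessions/phases.
#' @return an object of class `crew_session`.
#' @export
crew_session <- function(rec1, rec2, crew_id = "crew",
                         crew_type = c("REAL", "FAKE"),
                         experience = NA_character_, ratings = NULL,
                         provenance = NULL) {
  crew_type <- match.arg(crew_type)
  stopifnot(inherits(rec1, "eeg_recording"), inherits(rec2, "eeg_recording"))
  if (rec1$fs != rec2$fs) stop("operators recorded at different sampling rates")
  if (crew_type == "REAL" && ncol(rec1$samples) != ncol(rec2$samples)) {
    stop("REAL crews must have time-aligned, equal-length recordings")
  }
  if (!is.na(experience)) experience <- match.arg(experience, c("EXP", "UNEXP"))
  structure(list(rec1 = rec1, rec2 = rec2, crew_id = crew_id,
                 crew_type = crew_type, experience = experience,
                 ratings = ratings, provenance = provenance),
            class = "crew_session")
}

#' @export
print.crew_session <- function(x, ...) {
  cat(sprintf("<crew_session> %s (%s%s): operators %s + %s, %.1f s\n",
              x$crew_id, x$crew_type,
              if (!is.na(x$experience)) paste0(", ", x$experience) else "",
              x$rec1$operator_id, x$rec2$operator_id,
              min(recording_duration(x$rec1), recording_duration(x$rec2))))
  invisible(x)
}
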