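#' Crop a recording to a time interval
#'
#' @param rec an [eeg_recording].
#' @param start_s,end_s interval in seconds (clipped to the recording).
#' @return an [eeg_recording] holding the samples in `[start_s, end_s)`;
#'   annotations are dropped.
#' @export
crop_recording <- function(rec, start_s, end_s) {
  stopifnot(inherits(rec, "eeg_recording"), start_s < end_s)
  i0 <- max(1L, round(start_s * rec$fs) + 1L)
  i1 <- min(ncol(rec$samples), round(end_s * rec$fs))
  eeg_recording(rec$samples[, i0:i1, drop = FALSE], rec$fs,
                rec$channel_labels, NULL, rec$operator_id, rec$session_id)
}

# Eyes-closed segment of a recording, from its own annotations.
.eyes_closed_segment <- function(rec, label = "eyes_closed") {
  ann <- rec$phase_annotations
  if (is.null(ann) || !label %in% ann$label) return(NULL)
  row <- ann[ann$label == label, ][1L, ]
  crop_recording(rec, row$start_s, row$end_s)
}

#' Full per-crew cooperation analysis
#'
#' Runs the whole chain on one crew session: channel exclusion, zero-phase
#' notch + band-pass filtering, 1-s epoching with the +-80 microvolt artifact
#' rule, per-operator IAF estimation from the eyes-closed phase (fallback 10
#' Hz when absent), IAF-anchored W(t) and AW(t) features, frontal and
#' parietal full-band CCI series, the MICI series, and the
#' calibration-median thresholds with cooperation-time percentages for both
#' indices.
#'
#' @param session a [crew_session] of raw recordings.
#' @param cci_window_s,cci_step_s CCI sliding-window length/step in seconds
#'   (default 10/10; windows should divide the phase durations so that every
#'   window falls wholly inside one phase).
#' @param feature_window_s W/AW window in seconds (default 1).
#' @param mici_block_s MICI block length in seconds (default 30; blocks
#'   should divide the phase durations).
#' @param k nearest-neighbour count for the MI estimator (default 4).
#' @param spec a [filter_spec].
#' @param exclude channels excluded before analysis (default AF7, AF8).
#' @param amp_threshold_uV artifact threshold (default 80).
#' @param calibration_phases,cooperation_phase phase labels used for the
#'   threshold and the cooperation-time percentage.
#' @return an object of class `crew_analysis`: IAFs, epoched data, feature
#'   series, CCI/MICI series, thresholds, and cooperation-time percentages.
#' @export
analyze_crew <- function(session, cci_window_s = 10, cci_step_s = cci_window_s,
                         feature_window_s = 1, mici_block_s = 30, k = 4L,
                         spec = filter_spec(), exclude = c("AF7", "AF8"),
                         amp_threshold_uV = 80,
                         calibration_phases = c("low_diff", "high_diff"),
                         cooperation_phase = "cooperation") {
  stopifnot(inherits(session, "crew_session"))
  ann <- session$rec1$phase_annotations
  if (is.null(ann)) stop("session has no phase annotations")

  ops <- list(session$rec1, session$rec2)
  filtered <- vector("list", 2L)
  epoched <- vector("list", 2L)
  iaf <- numeric(2L)
  W <- AW <- vector("list", 2L)
  for (i in 1:2) {
    rec <- exclude_channels(ops[[i]], intersect(exclude, ops[[i]]$channel_labels),
                            check_required = TRUE)
    filt <- bandpass_notch(rec, spec)
    filtered[[i]] <- filt
    epoched[[i]] <- epoch_and_mask(filt, 1, amp_threshold_uV)
    ec <- .eyes_closed_segment(filt)
    iaf[i] <- if (is.null(ec)) {
      warning("no eyes_closed phase for operator ", i, "; using IAF = 10 Hz")
      10
    } else {
      estimate_iaf(ec)
    }
    scheme <- bands_from_iaf(iaf[i])
    W[[i]] <- workload_index(epoched[[i]], scheme, feature_window_s)
    AW[[i]] <- approach_withdrawal_index(epoched[[i]], scheme, feature_window_s)
  }

  fsession <- session
  fsession$rec1 <- filtered[[1L]]
  fsession$rec2 <- filtered[[2L]]
  masks <- list(epoched[[1L]]$artifact_mask, epoched[[2L]]$artifact_mask)
  cci_frontal <- cci_series(fsession, .frontal_channels, band = NULL,
                            window_s = cci_window_s, step_s = cci_step_s,
                            artifact_masks = masks)
  cci_parietal <- cci_series(fsession, .parietal_channels, band = NULL,
                             window_s = cci_window_s, step_s = cci_step_s,
                             artifact_masks = masks)
  mici <- mici_series(W[[1L]], AW[[1L]], W[[2L]], AW[[2L]],
                      block_s = mici_block_s, k = k,
                      min_windows = min(30L, floor(mici_block_s / feature_window_s)))

  thr_cci <- cooperation_threshold(cci_frontal, ann, calibration_phases)
  thr_mici <- cooperation_threshold(mici, ann, calibration_phases)
  pct_cci <- cooperation_time_pct(cci_frontal, thr_cci, ann, cooperation_phase)
  pct_mici <- cooperation_time_pct(mici, thr_mici, ann, cooperation_phase)

  structure(list(
    crew_id = session$crew_id, crew_type = session$crew_type,
    experience = session$experience, ratings = session$ratings,
    phase_annotations = ann, iaf = iaf,
    W = W, AW = AW, cci_frontal = cci_frontal, cci_parietal = cci_parietal,
    mici = mici, threshold = c(CCI = thr_cci, MICI = thr_mici),
    pct_cooperation_time = c(CCI = pct_cci, MICI = pct_mici)),
    class = "crew_analysis")
}

#' @export
print.crew_analysis <- function(x, ...) {
  cat(sprintf("<crew_analysis> %s (%s%s)\n", x$crew_id, x$crew_type,
              if (!is.na(x$experience)) paste0(", ", x$experience) else ""))
  cat(sprintf("  IAF: %.2f / %.2f Hz\n", x$iaf[1], x$iaf[2]))
  cat(sprintf("  thresholds: CCI %.4f, MICI %.4f nats\n",
              x$threshold["CCI"], x$threshold["MICI"]))
  cat(sprintf("  %%-cooperation time: CCI %.1f%%, MICI %.1f%%\n",
              x$pct_cooperation_time["CCI"], x$pct_cooperation_time["MICI"]))
  invisible(x)
}

# Per-phase mean of a feature series, one row per phase label.
.phase_means <- function(series, ann, phases) {
  vapply(phases, function(ph) {
    s <- filter_phase(series, ann, ph)
    mean(s)
  }, numeric(1))
}

#' Simulate and analyse a multi-crew experiment
#'
#' Desk-scale analogue of an 8-crew study: simulates `n_exp` high-coupling
#' ("EXP"-like) and `n_unexp` low-coupling ("UNEXP"-like) crews (coupling and
#' correlated latent states active during the cooperation phase only),
#' analyses each with [analyze_crew()], constructs FAKE surrogate crews and
#' analyses those, and assembles the group-level statistics: EXP-vs-UNEXP
#' comparisons of cooperation time, the index-vs-rating Pearson correlation,
#' REAL-vs-FAKE phase ANOVAs, and REAL/FAKE cooperation-vs-calibration paired
#' contrasts.
#'
#' @param n_exp,n_unexp crews per group (default 4 each).
#' @param coupling_exp,coupling_unexp cooperation-phase coupling of the two
#'   groups (defaults 0.8 / 0.3).
#' @param shared_exp,shared_unexp cooperation-phase latent-state correlation
#'   of the two groups (defaults = the couplings).
#' @param seed master RNG seed; each crew derives its own sub-seed.
#' @param phase_s duration of each task phase in seconds (default 120).
#' @param observer_sd observer noise on the behavioural ratings (default 0.5).
#' @param n_fake number of FAKE crews (default `n_exp + n_unexp`).
#' @param ... passed to [analyze_crew()].
#' @return an object of class `coop_report`.
#' @export
synthetic_crew_experiment <- function(n_exp = 4L, n_unexp = 4L,
                                      coupling_exp = 0.8, coupling_unexp = 0.3,
                                      shared_exp = coupling_exp,
                                      shared_unexp = coupling_unexp,
                                      seed = 1L, phase_s = 120,
                                      observer_sd = 0.5,
                                      n_fake = n_exp + n_unexp, ...) {
  n_crews <- n_exp + n_unexp
  groups <- rep(c("EXP", "UNEXP"), c(n_exp, n_unexp))
  sessions <- vector("list", n_crews)
  analyses <- vector("list", n_crews)
  phases <- data.frame(
    label = c("eyes_closed", "low_diff", "high_diff", "cooperation"),
    duration_s = c(60, phase_s, phase_s, phase_s))
  for (i in seq_len(n_crews)) {
    coup <- if (groups[i] == "EXP") coupling_exp else coupling_unexp
    shared <- if (groups[i] == "EXP") shared_exp else shared_unexp
    sc <- dyad_scenario(phases = phases, phase_coupling = coup,
                        shared_state_corr = shared,
                        seed = seed * 1000L + i)
    sim <- simulate_dyad(sc)
    ratings <- simulate_rating_series(sim$truth, observer_sd = observer_sd)
    s <- sim$session
    s$crew_id <- sprintf("crew-%02d", i)
    s$experience <- groups[i]
    s$ratings <- ratings
    # distinct operator ids so surrogate pairings are traceable
    s$rec1$operator_id <- sprintf("crew%02d-op1", i)
    s$rec2$operator_id <- sprintf("crew%02d-op2", i)
    sessions[[i]] <- s
    a <- analyze_crew(s, ...)
    a$experience <- groups[i]
    analyses[[i]] <- a
  }
  fake_sessions <- make_fake_crews(sessions, n_fake, seed = seed + 7L)
  fake_analyses <- lapply(fake_sessions, analyze_crew, ...)

  pct <- t(vapply(analyses, `[[`, numeric(2), "pct_cooperation_time"))
  exp_idx <- groups == "EXP"
  # group-level statistics need enough crews; smaller designs still return
  # the per-crew table, with the tests marked unavailable
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  cmp_mici <- safe(compare_groups(pct[exp_idx, "MICI"], pct[!exp_idx, "MICI"]))
  cmp_cci <- safe(compare_groups(pct[exp_idx, "CCI"], pct[!exp_idx, "CCI"]))

  crew_rating <- vapply(sessions, function(s) mean(s$ratings$rating), numeric(1))
  rc_mici <- safe(stats::cor.test(pct[, "MICI"], crew_rating))
  rc_cci <- safe(stats::cor.test(pct[, "CCI"], crew_rating))

  phase_set <- c("low_diff", "high_diff", "cooperation")
  collect <- function(anas, what, type) {
    do.call(rbind, lapply(seq_along(anas), function(i) {
      m <- .phase_means(anas[[i]][[what]], anas[[i]]$phase_annotations, phase_set)
      data.frame(crew = paste0(type, "-", i), crew_type = type,
                 phase = phase_set, value = m)
    }))
  }
  long_cci <- rbind(collect(analyses, "cci_frontal", "REAL"),
                    collect(fake_analyses, "cci_frontal", "FAKE"))
  long_mici <- rbind(collect(analyses, "mici", "REAL"),
                     collect(fake_analyses, "mici", "FAKE"))
  anova_cci <- phase_anova(long_cci$value, long_cci$phase, long_cci$crew,
                           group = long_cci$crew_type)
  anova_mici <- phase_anova(long_mici$value, long_mici$phase, long_mici$crew,
                            group = long_mici$crew_type)

  # cooperation-vs-calibration elevation, paired at the window level:
  # window k of the cooperation phase against the mean of window k of the
  # two calibration phases, pooled over the crews of a group
  window_contrast <- function(anas, what) {
    coop <- calib <- numeric(0)
    for (a in anas) {
      per_phase <- lapply(c("low_diff", "high_diff", "cooperation"), function(p) {
        s <- filter_phase(a[[what]], a$phase_annotations, p)
        ifelse(s$valid_mask, s$values, NA_real_)
      })
      nk <- min(lengths(per_phase))
      cw <- per_phase[[3]][seq_len(nk)]
      kw <- (per_phase[[1]][seq_len(nk)] + per_phase[[2]][seq_len(nk)]) / 2
      ok <- !is.na(cw) & !is.na(kw)
      coop <- c(coop, cw[ok])
      calib <- c(calib, kw[ok])
    }
    compare_groups(coop, calib, paired = TRUE)
  }
  exp_anas <- analyses[exp_idx]
  unexp_anas <- analyses[!exp_idx]
  elev <- list(
    cci_real_exp = window_contrast(exp_anas, "cci_frontal"),
    cci_real_unexp = window_contrast(unexp_anas, "cci_frontal"),
    cci_real = window_contrast(analyses, "cci_frontal"),
    cci_fake = window_contrast(fake_analyses, "cci_frontal"),
    mici_real_exp = window_contrast(exp_anas, "mici"),
    mici_real_unexp = window_contrast(unexp_anas, "mici"),
    mici_real = window_contrast(analyses, "mici"),
    mici_fake = window_contrast(fake_analyses, "mici"))

  structure(list(
    seed = seed, groups = groups, analyses = analyses,
    fake_analyses = fake_analyses,
    pct_cooperation_time = data.frame(crew = vapply(sessions, `[[`, character(1), "crew_id"),
                                      experience = groups,
                                      CCI = pct[, "CCI"], MICI = pct[, "MICI"],
                                      rating = crew_rating),
    group_comparison = list(MICI = cmp_mici, CCI = cmp_cci),
    rating_correlation = list(
      MICI = if (!is.null(rc_mici)) list(r = unname(rc_mici$estimate),
                                         p = rc_mici$p.value, n = n_crews),
      CCI = if (!is.null(rc_cci)) list(r = unname(rc_cci$estimate),
                                       p = rc_cci$p.value, n = n_crews)),
    phase_table = list(CCI = long_cci, MICI = long_mici),
    anova = list(CCI = anova_cci, MICI = anova_mici),
    elevation = elev), class = "coop_report")
}

#' @export
print.coop_report <- function(x, ...) {
  cat("<coop_report>", length(x$analyses), "REAL crews (",
      sum(x$groups == "EXP"), "EXP /", sum(x$groups == "UNEXP"), "UNEXP ),",
      length(x$fake_analyses), "FAKE crews\n")
  cat("\n%-cooperation time by crew:\n")
  print(x$pct_cooperation_time, row.names = FALSE, digits = 3)
  if (!is.null(x$group_comparison$MICI)) {
    cat("\nEXP vs UNEXP cooperation time:\n  MICI: ")
    print(x$group_comparison$MICI)
    cat("  CCI:  ")
    print(x$group_comparison$CCI)
  }
  if (!is.null(x$rating_correlation$MICI)) {
    cat(sprintf("\nIndex vs behavioural rating (Pearson):\n  MICI: r = %.3f, p = %.3g\n  CCI:  r = %.3f, p = %.3g\n",
                x$rating_correlation$MICI$r, x$rating_correlation$MICI$p,
                x$rating_correlation$CCI$r, x$rating_correlation$CCI$p))
  }
  cat("\nREAL-vs-FAKE x phase ANOVA (CCI):\n")
  print(x$anova$CCI)
  cat("\nREAL-vs-FAKE x phase ANOVA (MICI):\n")
  print(x$anova$MICI)
  cat("\nCooperation-phase elevation (cooperation vs calibration, paired):\n")
  for (nm in names(x$elevation)) {
    cat(sprintf("  %-9s p = %.4g\n", nm, x$elevation[[nm]]$p))
  }
  invisible(x)
}

#' Write a cooperation report to JSON
#'
#' Serialises the numeric content of a [synthetic_crew_experiment()] report
#' (cooperation-time table, group comparisons, rating correlations, ANOVA
#' tables, elevation contrasts) deterministically, so identical seeds yield
#' byte-identical files.
#'
#' @param report a `coop_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "coop_report"))
  strip <- function(tst) {
    if (is.null(tst)) return(NULL)
    tst[c("test", "statistic", "p", "effect_size", "effect_name")]
  }
  out <- list(
    seed = report$seed,
    pct_cooperation_time = report$pct_cooperation_time,
    group_comparison = lapply(report$group_comparison, strip),
    rating_correlation = report$rating_correlation,
    anova = lapply(report$anova, function(a) {
      list(table = a$table, resid_normality_p = a$resid_normality_p,
           homoscedasticity_p = a$homoscedasticity_p,
           rank_alternative = a$rank_alternative)
    }),
    elevation = lapply(report$elevation, strip))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a feature series to tidy CSV
#'
#' Columns: `window_start_s`, `kind`, `band`, `operator`, `value`, `valid`.
#'
#' @param x a [feature_series] (or list of them, row-bound).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  if (inherits(x, "feature_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
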