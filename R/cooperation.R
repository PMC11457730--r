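#' Calibration-median cooperation threshold
#'
#' The cooperation threshold for an index is the median of the index over all
#' valid windows of the calibration phases (the low- and high-difficulty
#' tasks each operator performed alone), pooled. For an even number of
#' windows the median is the mean of the central pair (the standard
#' convention; thresholds depend on it, so it is fixed here).
#'
#' @param index a [feature_series] spanning the session.
#' @param phase_annotations data.frame with `label`, `start_s`, `end_s`.
#' @param calibration_phases labels of the calibration phases (default
#'   `c("low_diff", "high_diff")`).
#' @return the threshold (scalar).
#' @export
cooperation_threshold <- function(index, phase_annotations,
                                  calibration_phases = c("low_diff", "high_diff")) {
  calib <- filter_phase(index, phase_annotations, calibration_phases)
  v <- calib$values[calib$valid_mask]
  if (length(v) < 2L) stop("need >= 2 valid calibration windows, got ", length(v))
  stats::median(v)
}

#' Percentage of cooperation time
#'
#' The fraction (as a percentage) of valid windows within a phase in which
#' the cooperation index lies strictly above the threshold. Ties count as
#' non-cooperative (conservative).
#'
#' @param index a [feature_series].
#' @param threshold scalar threshold, normally from
#'   [cooperation_threshold()].
#' @param phase_annotations data.frame with `label`, `start_s`, `end_s`; NULL
#'   to use all windows of `index`.
#' @param phases phase label(s) to evaluate (default `"cooperation"`).
#' @return percentage in \[0, 100\].
#' @export
cooperation_time_pct <- function(index, threshold, phase_annotations = NULL,
                                 phases = "cooperation") {
  x <- if (is.null(phase_annotations)) index
    else filter_phase(index, phase_annotations, phases)
  v <- x$values[x$valid_mask]
  if (length(v) < 1L) stop("no valid windows in phase(s): ",
                           paste(phases, collapse = ", "))
  100 * mean(v > threshold)
}

#' Construct surrogate (FAKE) crews
#'
#' Builds no-cooperation surrogate pairings by randomising operators across
#' crews and/or experimental phases: each FAKE crew pairs operators drawn
#' from different REAL crews, or the same crew with mismatched phase
#' alignment (one operator's recording circularly shifted by one phase
#' block), so that by construction no shared stimulus links the pair. A FAKE
#' crew never reproduces a REAL pairing with matched phases. Pair lengths are
#' equalised by truncation to the shorter member. Provenance (source crews
#' and shift) is recorded on each surrogate.
#'
#' @param sessions list of REAL [crew_session] objects (>= 2).
#' @param n_fake number of surrogate crews (default `length(sessions)`).
#' @param seed RNG seed for the pairing draw.
#' @return list of [crew_session] objects with `crew_type = "FAKE"`.
#' @export
make_fake_crews <- function(sessions, n_fake = length(sessions), seed = 1L) {
  stopifnot(length(sessions) >= 2L,
            all(vapply(sessions, inherits, logical(1), "crew_session")))
  pool <- list()
  for (s in sessions) {
    pool[[length(pool) + 1L]] <- list(rec = s$rec1, crew = s$crew_id)
    pool[[length(pool) + 1L]] <- list(rec = s$rec2, crew = s$crew_id)
  }
  real_pairs <- vapply(sessions, function(s) {
    paste(sort(c(s$rec1$operator_id, s$rec2$operator_id)), collapse = "|")
  }, character(1))
  with_preserved_seed(seed, {
    fakes <- vector("list", n_fake)
    attempts <- 0L
    i <- 1L
    while (i <= n_fake) {
      attempts <- attempts + 1L
      if (attempts > 1000L * n_fake) {
        stop("cannot build FAKE crews avoiding REAL pairings from this pool")
      }
      pick <- sample.int(length(pool), 2L)
      a <- pool[[pick[1L]]]
      b <- pool[[pick[2L]]]
      if (a$crew == b$crew) next   # cross-crew pairings only
      key <- paste(sort(c(a$rec$operator_id, b$rec$operator_id)), collapse = "|")
      if (key %in% real_pairs) next
      n_min <- min(ncol(a$rec$samples), ncol(b$rec$samples))
      trim <- function(r) {
        dur <- n_min / r$fs
        ann <- r$phase_annotations
        if (!is.null(ann)) {
          ann <- ann[ann$start_s < dur, , drop = FALSE]
          ann$end_s <- pmin(ann$end_s, dur)
        }
        eeg_recording(r$samples[, seq_len(n_min), drop = FALSE], r$fs,
                      r$channel_labels, ann, r$operator_id, r$session_id)
      }
      fakes[[i]] <- crew_session(
        trim(a$rec), trim(b$rec), crew_id = sprintf("fake-%02d", i),
        crew_type = "FAKE",
        provenance = data.frame(operator = c(a$rec$operator_id, b$rec$operator_id),
                                source_crew = c(a$crew, b$crew)))
      i <- i + 1L
    }
    fakes
  })
}

# Rank-biserial effect size for unpaired (from U) and paired (from signed ranks).
.rank_biserial_unpaired <- function(u, n1, n2) 1 - 2 * u / (n1 * n2)
.rank_biserial_paired <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

#' Normality-gated two-group comparison
#'
#' Runs Shapiro-Wilk on each group at alpha = 0.05; if both pass, a Student
#' t-test (paired or unpaired per `paired`) is used, otherwise the rank test
#' (Mann-Whitney, or Wilcoxon signed-rank when paired). Constant groups, for
#' which Shapiro-Wilk is undefined, fall back to the rank test with a
#' warning. The effect size is Cohen's d for the t-test and the rank-biserial
#' correlation for the rank tests.
#'
#' @param values_a,values_b numeric vectors (>= 3 values each; equal length
#'   when `paired`).
#' @param paired logical (default FALSE).
#' @param alpha normality-test level (default 0.05).
#' @return a list (class `coop_test`) with `test`, `statistic`, `p`,
#'   `effect_size`, `effect_name`, `normal_a`, `normal_b`, `n`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE, alpha = 0.05) {
  stopifnot(length(values_a) >= 3L, length(values_b) >= 3L)
  if (paired && length(values_a) != length(values_b)) {
    stop("paired comparison needs equal-length groups")
  }
  sw_p <- function(v) {
    if (stats::sd(v) < 1e-12) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  pa <- sw_p(values_a)
  pb <- sw_p(values_b)
  degenerate <- is.na(pa) || is.na(pb)
  if (degenerate) {
    warning("constant group: Shapiro-Wilk undefined, falling back to rank test")
  }
  normal <- !degenerate && pa > alpha && pb > alpha
  if (normal) {
    tt <- stats::t.test(values_a, values_b, paired = paired)
    pooled_sd <- if (paired) stats::sd(values_a - values_b)
      else sqrt(((length(values_a) - 1) * stats::var(values_a) +
                 (length(values_b) - 1) * stats::var(values_b)) /
                (length(values_a) + length(values_b) - 2))
    d <- (mean(values_a) - mean(values_b)) / pooled_sd
    res <- list(test = if (paired) "paired t-test" else "unpaired t-test",
                statistic = unname(tt$statistic), p = tt$p.value,
                effect_size = d, effect_name = "Cohen's d")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, paired = paired,
                                              exact = FALSE))
    es <- if (paired) .rank_biserial_paired(values_a - values_b)
      else .rank_biserial_unpaired(unname(wt$statistic),
                                   length(values_a), length(values_b))
    res <- list(test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney",
                statistic = unname(wt$statistic), p = wt$p.value,
                effect_size = es, effect_name = "rank-biserial r")
  }
  res$normal_a <- pa
  res$normal_b <- pb
  res$n <- c(length(values_a), length(values_b))
  structure(res, class = "coop_test")
}

#' @export
print.coop_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s); %s = %.3g\n",
              x$test, x$statistic, x$p, paste(x$n, collapse = "/"),
              x$effect_name, x$effect_size))
  invisible(x)
}

#' Correlation between a cooperation index and behavioural ratings
#'
#' Aggregates the index (mean of valid windows) to the rating cadence, aligns
#' it with the rating series, and reports the Pearson correlation over
#' jointly valid pairs.
#'
#' @param index a [feature_series].
#' @param ratings data.frame with `window_start_s` and a rating column
#'   (`rating` by default).
#' @param cadence_s rating cadence in seconds (default 30).
#' @param rating_col rating column name (default `"rating"`).
#' @return list with `r`, `p`, `n` and the aligned data.frame (`pairs`).
#' @export
rating_correlation <- function(index, ratings, cadence_s = 30,
                               rating_col = "rating") {
  stopifnot(inherits(index, "feature_series"),
            all(c("window_start_s", rating_col) %in% names(ratings)))
  if (stats::sd(ratings[[rating_col]]) < 1e-12) {
    stop("zero-variance ratings: correlation undefined")
  }
  agg <- vapply(ratings$window_start_s, function(t0) {
    sel <- index$start_times >= t0 - 1e-9 &
      index$start_times + index$window_s <= t0 + cadence_s + 1e-9 &
      index$valid_mask
    if (!any(sel)) NA_real_ else mean(index$values[sel])
  }, numeric(1))
  ok <- !is.na(agg)
  if (sum(ok) < 5L) stop("fewer than 5 aligned index/rating pairs")
  ct <- stats::cor.test(agg[ok], ratings[[rating_col]][ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       pairs = data.frame(window_start_s = ratings$window_start_s[ok],
                          index = agg[ok],
                          rating = ratings[[rating_col]][ok]))
}

# omega-squared effect size from a one-way (or multi-term) aov fit
.omega_sq <- function(fit) {
  tab <- stats::anova(fit)
  ss_eff <- tab$`Sum Sq`[seq_len(nrow(tab) - 1L)]
  df_eff <- tab$Df[seq_len(nrow(tab) - 1L)]
  ms_err <- tab$`Mean Sq`[nrow(tab)]
  ss_tot <- sum(tab$`Sum Sq`)
  (ss_eff - df_eff * ms_err) / (ss_tot + ms_err)
}

#' Phase comparison of a cooperation index by ANOVA
#'
#' Compares index summaries across experimental phases (and optionally
#' between REAL and FAKE crews) with a fixed-effects ANOVA, after checking
#' the assumptions (Shapiro-Wilk on residuals, Bartlett homoscedasticity).
#' Assumption failures are reported and the analysis proceeds with a logged
#' caveat, alongside a rank-based alternative (Kruskal-Wallis one-way, or
#' Friedman when `friedman = TRUE` and the design is complete blocks by
#' crew).
#'
#' @param values numeric vector of index summaries (one per crew x phase).
#' @param phase factor/character of phase labels, same length.
#' @param crew factor/character of crew identifiers, same length.
#' @param group optional second factor (e.g. REAL/FAKE) for a two-way layout.
#' @param friedman also run a Friedman test on the crew-blocked design
#'   (default FALSE).
#' @return list (class `coop_anova`) with the ANOVA table (`F`, `p`,
#'   `omega_sq` per term), assumption checks, and the rank-based alternative.
#' @export
phase_anova <- function(values, phase, crew, group = NULL, friedman = FALSE) {
  df <- data.frame(value = values, phase = factor(phase), crew = factor(crew))
  if (nlevels(df$phase) < 2L) stop("need >= 2 phases")
  if (nlevels(df$crew) < 3L) stop("need >= 3 crews")
  if (!is.null(group)) df$group <- factor(group)
  fit <- if (is.null(group)) stats::aov(value ~ phase, data = df)
    else stats::aov(value ~ group * phase, data = df)
  tab <- stats::anova(fit)
  terms <- rownames(tab)[seq_len(nrow(tab) - 1L)]
  res <- data.frame(term = terms,
                    F = tab$`F value`[seq_len(length(terms))],
                    p = tab$`Pr(>F)`[seq_len(length(terms))],
                    omega_sq = .omega_sq(fit))
  resid_norm_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                           error = function(e) NA_real_)
  homosked_p <- tryCatch(stats::bartlett.test(value ~ phase, data = df)$p.value,
                         error = function(e) NA_real_)
  caveat <- NULL
  if (!is.na(resid_norm_p) && resid_norm_p < 0.05) {
    caveat <- c(caveat, "residual normality rejected (Shapiro-Wilk p < 0.05)")
  }
  if (!is.na(homosked_p) && homosked_p < 0.05) {
    caveat <- c(caveat, "homoscedasticity rejected (Bartlett p < 0.05)")
  }
  rank_alt <- if (friedman) {
    complete <- all(table(df$crew, df$phase) == 1L)
    if (!complete) stop("Friedman test needs one value per crew x phase")
    ft <- stats::friedman.test(value ~ phase | crew, data = df)
    list(test = "Friedman", statistic = unname(ft$statistic), p = ft$p.value)
  } else {
    kt <- stats::kruskal.test(value ~ phase, data = df)
    list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
         p = kt$p.value)
  }
  structure(list(table = res, resid_normality_p = resid_norm_p,
                 homoscedasticity_p = homosked_p, caveats = caveat,
                 rank_alternative = rank_alt, n = nrow(df)),
            class = "coop_anova")
}

#' @export
print.coop_anova <- function(x, ...) {
  cat("ANOVA (n =", x$n, "):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  residual normality p = %.3g, homoscedasticity p = %.3g\n",
              x$resid_normality_p, x$homoscedasticity_p))
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  cat(sprintf("  rank alternative: %s, statistic = %.4g, p = %.4g\n",
              x$rank_alternative$test, x$rank_alternative$statistic,
              x$rank_alternative$p))
  invisible(x)
}
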