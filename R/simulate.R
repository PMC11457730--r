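#' Scenario description for a synthetic two-operator EEG session
#'
#' Defines everything the dyad simulator needs: session structure (ordered
#' phases with durations), sampling, per-operator individual alpha
#' frequencies, inter-operator phase coupling per band, per-phase workload and
#' asymmetry targets, the correlation of the two operators' latent cognitive
#' state drivers, background-noise shape and level, and blink-artifact
#' statistics. Identical scenario + seed produces bit-identical output.
#'
#' @param phases data.frame with columns `label`, `duration_s`; the session is
#'   the concatenation in order. Default: 60 s eyes_closed, 60 s low_diff,
#'   60 s high_diff, 60 s cooperation.
#' @param fs sampling rate in Hz (default 125). Must exceed twice the highest
#'   synthesised frequency (the beta band top, IAF + 16).
#' @param channels ordered channel labels (default AFz, AF3, AF4, AF7, AF8,
#'   Pz, P3, P4).
#' @param iaf_1,iaf_2 individual alpha frequency per operator, Hz (default 10).
#' @param phase_coupling scalar or named vector (`theta`, `alpha`, `beta`) in
#'   \[0, 1\]: 0 = independent band phases, 1 = locked.
#' @param coupling_phases phase labels during which the coupling is active
#'   (default `"cooperation"`; elsewhere coupling is 0). NULL = all phases.
#' @param workload_profile_1,workload_profile_2 named numeric: target
#'   mental-workload level W per phase label (dimensionless, > 0).
#' @param asymmetry_profile_1,asymmetry_profile_2 named numeric: target
#'   approach-withdrawal level AW per phase label (microvolts squared; must
#'   stay below `alpha_base_uV^2` in magnitude).
#' @param shared_state_corr correlation in \[-1, 1\] between the two operators'
#'   latent workload/asymmetry drivers (default 0).
#' @param noise_exponent 1/f spectral slope of the background noise
#'   (default 1).
#' @param noise_rms_uV background-noise RMS per channel in microvolts
#'   (default 2; 0 disables noise).
#' @param blink_rate blink-artifact rate in events/minute (default 0).
#' @param artifact_amp blink peak amplitude in microvolts (default 150).
#' @param alpha_base_uV frontal alpha base amplitude, microvolts (default 2).
#' @param parietal_alpha_uV parietal alpha amplitude, microvolts (default 4).
#' @param beta_uV beta oscillator amplitude, microvolts (default 1).
#' @param phase_jitter phase-diffusion rate of each free-running oscillator,
#'   rad/sqrt(s) (default 0.75, a Lorentzian linewidth of ~0.1 Hz: broad
#'   enough that band phases decorrelate over tens of seconds, narrow enough
#'   that windowed phase statistics are stable).
#' @param w_log_sd,aw_sd standard deviations of the latent log-workload and
#'   asymmetry fluctuations (defaults 0.4 and 0.8: second-scale state swings
#'   comparable to the between-phase target differences, so the latent states
#'   are recoverable through the spectral features).
#' @param state_ar AR(1) coefficient of the latent state processes at the 1-s
#'   epoch cadence (default 0.8, a ~5 s correlation time).
#' @param seed integer RNG seed (default 1).
#' @return an object of class `dyad_scenario`.
#' @export
dyad_scenario <- function(phases = data.frame(
                            label = c("eyes_closed", "low_diff", "high_diff",
                                      "cooperation"),
                            duration_s = c(60, 60, 60, 60)),
                          fs = 125, channels = .default_channels,
                          iaf_1 = 10, iaf_2 = 10,
                          phase_coupling = 0.5,
                          coupling_phases = "cooperation",
                          workload_profile_1 = NULL, workload_profile_2 = NULL,
                          asymmetry_profile_1 = NULL, asymmetry_profile_2 = NULL,
                          shared_state_corr = 0,
                          noise_exponent = 1, noise_rms_uV = 2,
                          blink_rate = 0, artifact_amp = 150,
                          alpha_base_uV = 2, parietal_alpha_uV = 4,
                          beta_uV = 1, phase_jitter = 0.75,
                          w_log_sd = 0.4, aw_sd = 0.8, state_ar = 0.8,
                          seed = 1L) {
  stopifnot(is.data.frame(phases), all(c("label", "duration_s") %in% names(phases)),
            all(phases$duration_s > 0))
  bands <- c("theta", "alpha", "beta")
  if (length(phase_coupling) == 1L && is.null(names(phase_coupling))) {
    phase_coupling <- stats::setNames(rep(phase_coupling, 3L), bands)
  }
  if (!all(bands %in% names(phase_coupling))) {
    stop("phase_coupling must be a scalar or named over theta/alpha/beta")
  }
  phase_coupling <- phase_coupling[bands]
  if (any(phase_coupling < 0 | phase_coupling > 1)) {
    stop("phase_coupling must lie in [0, 1], got ",
         paste(round(phase_coupling, 3), collapse = ", "))
  }
  if (shared_state_corr < -1 || shared_state_corr > 1) {
    stop("shared_state_corr must lie in [-1, 1]")
  }
  for (iaf in c(iaf_1, iaf_2)) {
    if (fs <= 2 * (iaf + 16)) {
      stop("fs = ", fs, " Hz too low for the beta band (needs > ",
           2 * (iaf + 16), " Hz)")
    }
  }
  default_w <- stats::setNames(rep(1.5, nrow(phases)), phases$label)
  default_aw <- function(sign) stats::setNames(rep(sign * 0.5, nrow(phases)),
                                               phases$label)
  fill <- function(x, default) {
    if (is.null(x)) return(default)
    missing <- setdiff(phases$label, names(x))
    if (length(missing)) stop("profile missing phase(s): ",
                              paste(missing, collapse = ", "))
    x[phases$label]
  }
  workload_profile_1 <- fill(workload_profile_1, default_w)
  workload_profile_2 <- fill(workload_profile_2, default_w)
  asymmetry_profile_1 <- fill(asymmetry_profile_1, default_aw(+1))
  asymmetry_profile_2 <- fill(asymmetry_profile_2, default_aw(-1))
  for (aw in c(asymmetry_profile_1, asymmetry_profile_2)) {
    if (abs(aw) >= alpha_base_uV^2) {
      stop("asymmetry target |", aw, "| must be < alpha_base_uV^2 = ",
           alpha_base_uV^2)
    }
  }
  structure(list(
    phases = phases, duration_s = sum(phases$duration_s), fs = fs,
    channels = channels, iaf_1 = iaf_1, iaf_2 = iaf_2,
    phase_coupling = phase_coupling, coupling_phases = coupling_phases,
    workload_profile_1 = workload_profile_1,
    workload_profile_2 = workload_profile_2,
    asymmetry_profile_1 = asymmetry_profile_1,
    asymmetry_profile_2 = asymmetry_profile_2,
    shared_state_corr = shared_state_corr,
    noise_exponent = noise_exponent, noise_rms_uV = noise_rms_uV,
    blink_rate = blink_rate, artifact_amp = artifact_amp,
    alpha_base_uV = alpha_base_uV, parietal_alpha_uV = parietal_alpha_uV,
    beta_uV = beta_uV, phase_jitter = phase_jitter,
    w_log_sd = w_log_sd, aw_sd = aw_sd, state_ar = state_ar,
    seed = as.integer(seed)), class = "dyad_scenario")
}

#' @export
print.dyad_scenario <- function(x, ...) {
  cat(sprintf("<dyad_scenario> %g s @ %g Hz, %d channels, seed %d\n",
              x$duration_s, x$fs, length(x$channels), x$seed))
  cat("  phases:  ", paste(sprintf("%s (%g s)", x$phases$label,
                                   x$phases$duration_s), collapse = ", "), "\n")
  cat("  coupling:", paste(sprintf("%s=%.2f", names(x$phase_coupling),
                                   x$phase_coupling), collapse = " "),
      "during", paste(x$coupling_phases %||% "all phases", collapse = "+"), "\n")
  cat(sprintf("  shared_state_corr = %.2f, noise %g uV rms (1/f^%g), blinks %g/min\n",
              x$shared_state_corr, x$noise_rms_uV, x$noise_exponent,
              x$blink_rate))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1/f^alpha noise by spectral shaping of white Gaussian noise, unit RMS.
.one_over_f_noise <- function(n, alpha) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  freq_idx <- c(1, seq_len(n - 1))          # avoid the DC singularity
  scale <- freq_idx^(-alpha / 2)
  scale[1] <- 0
  x <- Re(stats::fft(X * scale, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Stereotyped biphasic blink transient: one full sine cycle over 400 ms.
.blink_waveform <- function(fs, amp, dur = 0.4) {
  t <- seq_len(round(dur * fs)) / fs
  amp * sin(2 * pi * t / dur)
}

#' Simulate a two-operator EEG session with known ground truth
#'
#' Each operator's signal is a sum of band-limited oscillators (theta, alpha,
#' beta, centred in the operator's IAF-anchored bands) plus 1/f background
#' noise and optional blink transients. Operator 1's band phases are
#' free-running (linear advance plus phase diffusion); operator 2's phase in
#' each band is the circular mixture of its own free-running phase and
#' operator 1's phase with weight `phase_coupling` — so coupling 0 gives
#' independent phases, coupling 1 gives identical phases, and the circular
#' correlation of the generated phases increases monotonically in between.
#'
#' Oscillator amplitudes are set per 1-s epoch so that, on the clean signal,
#' the frontal-theta / parietal-alpha power ratio equals the realised
#' workload level and the AF4-minus-AF3 alpha power difference equals the
#' realised asymmetry level. Realised levels are the per-phase targets
#' modulated by latent AR(1) fluctuations whose innovations are correlated
#' across operators with `shared_state_corr`.
#'
#' Blink transients (400 ms biphasic, frontal channels, peak
#' `artifact_amp`) are placed to lie within single epochs, so the returned
#' event log is an exact oracle for the downstream amplitude-threshold
#' artifact mask.
#'
#' @param scenario a [dyad_scenario].
#' @return a list with elements `session` (a [crew_session] of two raw
#'   [eeg_recording]s with phase annotations) and `truth` (class
#'   `dyad_ground_truth`: per-band generated phases and coupling schedules,
#'   per-epoch latent and realised workload/asymmetry levels, and the blink
#'   event log).
#' @export
simulate_dyad <- function(scenario) {
  stopifnot(inherits(scenario, "dyad_scenario"))
  sc <- scenario
  fs <- sc$fs
  n_ep <- round(sc$duration_s)              # 1-s epochs
  spe <- round(fs)                          # samples per epoch
  n <- n_ep * spe
  bands <- c("theta", "alpha", "beta")

  ann <- data.frame(label = sc$phases$label,
                    start_s = cumsum(c(0, sc$phases$duration_s))[seq_len(nrow(sc$phases))],
                    end_s = cumsum(sc$phases$duration_s))
  epoch_phase <- rep(sc$phases$label, times = round(sc$phases$duration_s))
  sample_phase <- rep(epoch_phase, each = spe)

  with_preserved_seed(sc$seed, {
    # --- coupling schedule per band (per sample) -------------------------
    active <- if (is.null(sc$coupling_phases)) rep(TRUE, n)
      else sample_phase %in% sc$coupling_phases
    coupling <- lapply(stats::setNames(bands, bands), function(b) {
      ifelse(active, sc$phase_coupling[[b]], 0)
    })

    # --- band phases -----------------------------------------------------
    centre_freq <- function(iaf) c(theta = iaf - 4, alpha = iaf, beta = iaf + 9)
    f1 <- centre_freq(sc$iaf_1)
    f2 <- centre_freq(sc$iaf_2)
    t_samp <- (seq_len(n) - 1) / fs
    free_phase <- function(f) {
      drift <- cumsum(stats::rnorm(n, 0, sc$phase_jitter / sqrt(fs)))
      2 * pi * f * t_samp + stats::runif(1, -pi, pi) + drift
    }
    phases1 <- phases2 <- list()
    for (b in bands) {
      p1 <- free_phase(f1[[b]])
      p2_free <- free_phase(f2[[b]])
      cb <- coupling[[b]]
      z <- (1 - cb) * exp(1i * p2_free) + cb * exp(1i * p1)
      p2 <- ifelse(Mod(z) < 1e-12, p2_free, Arg(z))
      phases1[[b]] <- wrap_phase(p1)
      phases2[[b]] <- wrap_phase(p2)
    }

    # --- latent workload / asymmetry states (per epoch) ------------------
    # innovations correlated only while the coupling schedule is active
    ep_active <- if (is.null(sc$coupling_phases)) rep(TRUE, n_ep)
      else epoch_phase %in% sc$coupling_phases
    corr_innov <- function(rho) {
      rho_t <- ifelse(ep_active, rho, 0)
      g <- stats::rnorm(n_ep)
      e1 <- stats::rnorm(n_ep)
      e2 <- stats::rnorm(n_ep)
      s <- sign(rho_t + 1e-300)
      r <- abs(rho_t)
      cbind(sqrt(r) * g + sqrt(1 - r) * e1,
            s * sqrt(r) * g + sqrt(1 - r) * e2)
    }
    ar1 <- function(innov, a) {
      z <- numeric(length(innov))
      z[1] <- innov[1]
      for (i in seq_along(innov)[-1]) z[i] <- a * z[i - 1] + sqrt(1 - a^2) * innov[i]
      z
    }
    iw <- corr_innov(sc$shared_state_corr)
    ia <- corr_innov(sc$shared_state_corr)
    z_w <- cbind(ar1(iw[, 1], sc$state_ar), ar1(iw[, 2], sc$state_ar))
    z_aw <- cbind(ar1(ia[, 1], sc$state_ar), ar1(ia[, 2], sc$state_ar))

    latent <- list()
    amp <- list()
    for (op in 1:2) {
      w_t <- unname(sc[[paste0("workload_profile_", op)]][epoch_phase])
      aw_t <- unname(sc[[paste0("asymmetry_profile_", op)]][epoch_phase])
      w_real <- w_t * exp(sc$w_log_sd * z_w[, op])
      aw_real <- aw_t + sc$aw_sd * z_aw[, op]
      aw_real <- pmax(pmin(aw_real, 0.95 * sc$alpha_base_uV^2),
                      -0.95 * sc$alpha_base_uV^2)
      latent[[op]] <- data.frame(epoch = seq_len(n_ep), phase = epoch_phase,
                                 z_w = z_w[, op], z_aw = z_aw[, op],
                                 W_target = w_t, AW_target = aw_t,
                                 W_real = w_real, AW_real = aw_real)
      # amplitudes realising the targets on the clean signal
      a_pa <- sc$parietal_alpha_uV
      amp[[op]] <- list(
        theta_frontal = a_pa * sqrt(w_real),
        alpha_af4 = sqrt(sc$alpha_base_uV^2 + aw_real),
        alpha_af3 = sqrt(sc$alpha_base_uV^2 - aw_real),
        alpha_frontal = rep(sc$alpha_base_uV, n_ep),
        alpha_parietal = rep(a_pa, n_ep),
        beta = rep(sc$beta_uV, n_ep))
    }

    # --- blinks (constrained inside single epochs, at most one per epoch:
    # a refractory constraint that also keeps the event log an exact oracle
    # for the amplitude mask) ---------------------------------------------
    n_blinks <- min(stats::rpois(1, sc$blink_rate / 60 * sc$duration_s), n_ep)
    blink_epoch <- if (n_blinks > 0) sample.int(n_ep, n_blinks, replace = FALSE)
      else integer(0)
    blink_offset <- stats::runif(n_blinks, 0, 0.6)
    blink_time <- (blink_epoch - 1) + blink_offset
    blinks <- data.frame(time_s = blink_time, epoch = blink_epoch)
    wave <- .blink_waveform(fs, sc$artifact_amp)
    blink_signal <- numeric(n)
    for (bti in seq_len(n_blinks)) {
      i0 <- round(blink_time[bti] * fs) + 1L
      idx <- i0:(i0 + length(wave) - 1L)
      blink_signal[idx] <- blink_signal[idx] + wave
    }

    # --- assemble channels ------------------------------------------------
    per_sample <- function(a) rep(a, each = spe)
    frontal_all <- c("AFz", "AF3", "AF4", "AF7", "AF8")
    build_op <- function(op) {
      ph <- if (op == 1) phases1 else phases2
      a <- amp[[op]]
      th <- per_sample(a$theta_frontal) * cos(ph$theta)
      be <- per_sample(a$beta) * cos(ph$beta)
      al_f <- per_sample(a$alpha_frontal) * cos(ph$alpha)
      al_3 <- per_sample(a$alpha_af3) * cos(ph$alpha)
      al_4 <- per_sample(a$alpha_af4) * cos(ph$alpha)
      al_p <- per_sample(a$alpha_parietal) * cos(ph$alpha)
      m <- matrix(0, length(sc$channels), n,
                  dimnames = list(sc$channels, NULL))
      for (ch in sc$channels) {
        base <- if (ch %in% frontal_all) {
          th + be + switch(ch, AF3 = al_3, AF4 = al_4, al_f)
        } else {
          al_p + be
        }
        noise <- if (sc$noise_rms_uV > 0) {
          sc$noise_rms_uV * .one_over_f_noise(n, sc$noise_exponent)
        } else 0
        blink <- if (ch %in% frontal_all) blink_signal else 0
        m[ch, ] <- base + noise + blink
      }
      m
    }
    m1 <- build_op(1)
    m2 <- build_op(2)

    rec1 <- eeg_recording(m1, fs, sc$channels, ann, operator_id = "op1",
                          session_id = sprintf("sim-seed%d", sc$seed))
    rec2 <- eeg_recording(m2, fs, sc$channels, ann, operator_id = "op2",
                          session_id = sprintf("sim-seed%d", sc$seed))
    session <- crew_session(rec1, rec2,
                            crew_id = sprintf("sim-crew-seed%d", sc$seed))
    truth <- structure(list(
      phases = list(op1 = phases1, op2 = phases2),
      coupling = coupling, latent = latent, blinks = blinks,
      fs = fs, epoch_length_s = 1, phase_annotations = ann,
      scenario = sc), class = "dyad_ground_truth")
    list(session = session, truth = truth)
  })
}

#' @export
print.dyad_ground_truth <- function(x, ...) {
  cat(sprintf("<dyad_ground_truth> %d samples @ %g Hz, %d blinks, bands: %s\n",
              length(x$phases$op1$theta), x$fs, nrow(x$blinks),
              paste(names(x$phases$op1), collapse = ", ")))
  invisible(x)
}

#' Simulated behavioural cooperation ratings
#'
#' Emulates an observer scoring the crew's cooperation once per rating window
#' (30 s by default): the score is an affine (hence monotone) map of the
#' windowed mean ground-truth phase coupling onto a 1-10 scale, one rating per
#' operator, each with independent additive observer noise. The crew-level
#' behavioural score is the mean of the two operators' ratings.
#'
#' @param truth a `dyad_ground_truth` from [simulate_dyad()].
#' @param window_s rating cadence in seconds (default 30); the trailing
#'   partial window is dropped.
#' @param observer_sd observer-noise standard deviation on the rating scale
#'   (default 0).
#' @param seed RNG seed for the observer noise (default: scenario seed + 1).
#' @return data.frame with `window_start_s`, `coupling` (windowed mean
#'   ground-truth coupling across bands), `rating_1`, `rating_2`, and `rating`
#'   (crew mean).
#' @export
simulate_rating_series <- function(truth, window_s = 30, observer_sd = 0,
                                   seed = NULL) {
  stopifnot(inherits(truth, "dyad_ground_truth"))
  n <- length(truth$coupling$theta)
  wlen <- round(window_s * truth$fs)
  if (wlen > n) stop("rating window longer than the session")
  n_win <- floor(n / wlen)
  mean_c <- Reduce(`+`, truth$coupling) / length(truth$coupling)
  wc <- vapply(seq_len(n_win), function(w) {
    mean(mean_c[((w - 1L) * wlen + 1L):(w * wlen)])
  }, numeric(1))
  if (is.null(seed)) seed <- truth$scenario$seed + 1L
  with_preserved_seed(seed, {
    r1 <- 1 + 9 * wc + stats::rnorm(n_win, 0, observer_sd)
    r2 <- 1 + 9 * wc + stats::rnorm(n_win, 0, observer_sd)
    data.frame(window_start_s = (seq_len(n_win) - 1L) * window_s,
               coupling = wc, rating_1 = r1, rating_2 = r2,
               rating = (r1 + r2) / 2)
  })
}

#' Write / read a dyad scenario as YAML
#'
#' Round-trips every field of a [dyad_scenario()], including the phase table
#' and the per-phase profiles, so scenarios can be version-controlled and fed
#' to the command-line interface.
#'
#' @param scenario a [dyad_scenario].
#' @param path YAML file path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a [dyad_scenario].
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "dyad_scenario"))
  x <- unclass(scenario)
  x$duration_s <- NULL # derived
  x$phases <- lapply(seq_len(nrow(scenario$phases)), function(i) {
    list(label = scenario$phases$label[i],
         duration_s = scenario$phases$duration_s[i])
  })
  for (f in grep("profile|phase_coupling", names(x), value = TRUE)) {
    x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$phases <- data.frame(
    label = vapply(x$phases, `[[`, character(1), "label"),
    duration_s = vapply(x$phases, `[[`, numeric(1), "duration_s"))
  for (f in grep("profile|phase_coupling", names(x), value = TRUE)) {
    x[[f]] <- unlist(x[[f]])
  }
  do.call(dyad_scenario, x)
}
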