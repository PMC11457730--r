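test_that("identical scenario and seed give bit-identical output", {
  sc <- quick_scenario(seed = 5, blink_rate = 4)
  a <- simulate_dyad(sc)
  b <- simulate_dyad(sc)
  expect_identical(a$session$rec1$samples, b$session$rec1$samples)
  expect_identical(a$session$rec2$samples, b$session$rec2$samples)
  expect_identical(a$truth$blinks, b$truth$blinks)
  # a different seed changes the data
  c <- simulate_dyad(quick_scenario(seed = 6, blink_rate = 4))
  expect_false(identical(a$session$rec1$samples, c$session$rec1$samples))
  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_dyad(sc)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(quick_scenario(coupling = 1.2), "\\[0, 1\\]")
  expect_error(dyad_scenario(shared_state_corr = -2), "\\[-1, 1\\]")
  expect_error(dyad_scenario(fs = 40), "beta band")
  expect_error(dyad_scenario(asymmetry_profile_1 = c(
    eyes_closed = 9, low_diff = 9, high_diff = 9, cooperation = 9)),
    "alpha_base")
})

test_that("locked oscillators give identical phases; independent ones near-zero correlation", {
  sc1 <- quick_scenario(seed = 8, coupling = 1, noise = 0,
                        coupling_phases = NULL)
  sim1 <- simulate_dyad(sc1)
  for (b in c("theta", "alpha", "beta")) {
    expect_equal(circular_correlation(sim1$truth$phases$op1[[b]],
                                      sim1$truth$phases$op2[[b]]), 1,
                 tolerance = 1e-9)
  }
  # coupling 0: generated phases decorrelated. The null width is set by the
  # phase-diffusion rate, not the sample count: over 300 s the inter-operator
  # phase difference makes few independent excursions, so |ccor| stays well
  # above an iid-uniform bound. A 100-seed Monte-Carlo of this construction
  # gives median 0.053, 95th percentile 0.166, max 0.197.
  vals <- sapply(1:20, function(s) {
    sim0 <- simulate_dyad(quick_scenario(seed = 400 + s, coupling = 0,
                                         phase_s = 100, noise = 0,
                                         coupling_phases = NULL))
    circular_correlation(sim0$truth$phases$op1$alpha,
                         sim0$truth$phases$op2$alpha)
  })
  expect_lt(median(abs(vals)), 0.1)
  expect_lt(max(abs(vals)), 0.25)
})

test_that("circular correlation of generated phases rises monotonically with coupling", {
  cc <- sapply(c(0, 0.5, 1), function(cp) {
    median(sapply(1:5, function(s) {
      sim <- simulate_dyad(quick_scenario(seed = 500 + s, coupling = cp,
                                          phase_s = 60, noise = 0,
                                          coupling_phases = NULL))
      circular_correlation(sim$truth$phases$op1$alpha,
                           sim$truth$phases$op2$alpha)
    }))
  })
  expect_true(all(diff(cc) > 0))
  expect_gt(cc[3], 0.99)
})

test_that("emitted spectra peak at the configured oscillator frequencies", {
  sim <- simulate_dyad(quick_scenario(seed = 12, phase_s = 60, noise = 1))
  fs <- sim$session$rec1$fs
  peak_near <- function(x, f0) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 15,
                            plot = FALSE, taper = 0)
    sel <- sp$freq > f0 - 2 & sp$freq < f0 + 2
    abs(sp$freq[sel][which.max(sp$spec[sel])] - f0)
  }
  # parietal alpha at IAF = 10; frontal theta at IAF - 4 = 6
  expect_lt(peak_near(sim$session$rec1$samples["Pz", ], 10), 0.5)
  expect_lt(peak_near(sim$session$rec1$samples["AFz", ], 6), 0.5)
})

test_that("ground truth is sample-aligned with the emitted recordings", {
  sc <- quick_scenario(seed = 13, phase_s = 20)
  sim <- simulate_dyad(sc)
  n <- ncol(sim$session$rec1$samples)
  for (b in c("theta", "alpha", "beta")) {
    expect_length(sim$truth$phases$op1[[b]], n)
    expect_length(sim$truth$coupling[[b]], n)
  }
  expect_identical(nrow(sim$truth$latent[[1]]), as.integer(sc$duration_s))
  # parietal signal reproduces the alpha oscillator phase sample for sample
  # (mean resultant of the phase error; circular-mean-free agreement measure)
  rec <- sim$session$rec1
  ph <- instantaneous_phase(rec, "Pz", band = c(8, 12))$phases
  mid <- seq(round(n * 0.25), round(n * 0.75))
  err <- ph[mid] - sim$truth$phases$op1$alpha[mid]
  expect_gt(mean(cos(err)), 0.9)
})

test_that("rating series is a monotone map of windowed coupling with seeded noise", {
  # constant coupling, zero noise -> constant ratings
  sim <- simulate_dyad(quick_scenario(seed = 14, coupling = 0.7,
                                      coupling_phases = NULL, phase_s = 30))
  r <- simulate_rating_series(sim$truth, window_s = 30, observer_sd = 0)
  expect_equal(diff(range(r$rating)), 0, tolerance = 1e-12)
  # coupling active only in cooperation -> strictly higher ratings there
  sim2 <- simulate_dyad(quick_scenario(seed = 15, coupling = 0.9, phase_s = 30))
  r2 <- simulate_rating_series(sim2$truth, window_s = 30, observer_sd = 0)
  expect_true(all(r2$rating[r2$coupling > 0] > r2$rating[r2$coupling == 0]))
  # non-decreasing in coupling (monotone map)
  expect_identical(order(r2$rating), order(r2$coupling))
  # noisy ratings: correlation with coupling matches brute-force recomputation
  r3 <- simulate_rating_series(sim2$truth, window_s = 10, observer_sd = 0.5,
                               seed = 77)
  expect_equal(cor(r3$rating, r3$coupling),
               cor(r3$coupling, (r3$rating_1 + r3$rating_2) / 2),
               tolerance = 1e-12)
  expect_error(simulate_rating_series(sim2$truth, window_s = 1e5), "longer")
})

test_that("blink injection matches the configured rate and the event log", {
  sc <- quick_scenario(seed = 16, phase_s = 20, blink_rate = 6, noise = 0)
  sim <- simulate_dyad(sc)          # 60 s at 6/min -> ~6 blinks
  n_blinks <- nrow(sim$truth$blinks)
  expect_gt(n_blinks, 0)
  expect_lt(n_blinks, 20)
  # blinks appear on frontal channels at the logged times
  for (i in seq_len(n_blinks)) {
    t0 <- sim$truth$blinks$time_s[i]
    idx <- round(t0 * 125) + seq_len(50)
    expect_gt(max(abs(sim$session$rec1$samples["AFz", idx])), 80)
  }
})

test_that("scenario YAML round-trips to an identical simulation", {
  sc <- quick_scenario(seed = 19, coupling = 0.6, blink_rate = 2, phase_s = 10)
  path <- tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, path)
  sc2 <- read_scenario_yaml(path)
  expect_equal(sc2$phase_coupling, sc$phase_coupling)
  expect_equal(sc2$phases, sc$phases)
  expect_identical(simulate_dyad(sc2)$session$rec1$samples,
                   simulate_dyad(sc)$session$rec1$samples)
  unlink(path)
})
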