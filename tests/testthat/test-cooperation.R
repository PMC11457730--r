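# shared fixture: a feature series on a 3-phase session
fs_fixture <- function(values, valid = !is.na(values), window_s = 10) {
  feature_series(values, window_s, (seq_along(values) - 1) * window_s,
                 kind = "CCI", valid_mask = valid)
}
ann3 <- data.frame(label = c("low_diff", "high_diff", "cooperation"),
                   start_s = c(0, 30, 60), end_s = c(30, 60, 90))

test_that("cooperation threshold is the pooled calibration median", {
  x <- fs_fixture(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 9, 9, 9))
  expect_equal(cooperation_threshold(x, ann3), median(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)))
  # even-n median = mean of the central pair
  y <- fs_fixture(c(0.1, 0.2, 0.3, 0.4, NA, NA, 9, 9, 9))
  expect_equal(cooperation_threshold(y, ann3), 0.25)
  # invalid windows are ignored entirely
  z <- fs_fixture(c(0.1, 50, 0.2, 0.3, NA, NA, 9, 9, 9),
                  valid = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(cooperation_threshold(z, ann3), 0.2)
  expect_error(cooperation_threshold(fs_fixture(c(NA, NA, NA, NA, NA, NA, 1, 1, 1)),
                                     ann3), "calibration windows")
})

test_that("cooperation time percentage uses strict exceedance over valid windows", {
  x <- fs_fixture(c(rep(0, 6), 1, 2, 3))
  ann_wide <- ann3
  expect_equal(cooperation_time_pct(fs_fixture(c(1, 2, 3, 4)), 2.5), 50)
  expect_equal(cooperation_time_pct(x, 2.5, ann_wide, "cooperation"), 100 / 3)
  expect_equal(cooperation_time_pct(x, 10, ann_wide, "cooperation"), 0)
  # ties are non-cooperative
  expect_equal(cooperation_time_pct(fs_fixture(c(2, 2, 3, 4)), 2), 50)
  expect_error(cooperation_time_pct(fs_fixture(c(NA, NA)), 1), "no valid")
})

test_that("threshold/percentage consistency: calibration sits near 50% by the median property", {
  set.seed(77)
  for (i in 1:10) {
    v <- c(runif(20), rep(9, 4))
    x <- fs_fixture(v, window_s = 90 / 24)
    ann <- data.frame(label = c("low_diff", "high_diff", "cooperation"),
                      start_s = c(0, 37.5, 75), end_s = c(37.5, 75, 90))
    thr <- cooperation_threshold(x, ann)
    pct <- cooperation_time_pct(x, thr, ann, c("low_diff", "high_diff"))
    expect_lte(pct, 50)
    expect_gte(pct, 50 - 100 / 20)
  }
})

test_that("FAKE crews avoid real pairings, are deterministic, and truncate lengths", {
  sims <- lapply(1:3, function(i) {
    sim <- simulate_dyad(quick_scenario(seed = 80 + i,
                                        phase_s = c(10, 10, 10 + 2 * i)[3]))
    s <- sim$session
    s$crew_id <- paste0("crew", i)
    s$rec1$operator_id <- paste0("c", i, "op1")
    s$rec2$operator_id <- paste0("c", i, "op2")
    s
  })
  fakes <- make_fake_crews(sims, n_fake = 6, seed = 9)
  expect_length(fakes, 6)
  real_keys <- sapply(sims, function(s)
    paste(sort(c(s$rec1$operator_id, s$rec2$operator_id)), collapse = "|"))
  for (f in fakes) {
    expect_identical(f$crew_type, "FAKE")
    key <- paste(sort(c(f$rec1$operator_id, f$rec2$operator_id)), collapse = "|")
    expect_false(key %in% real_keys)
    expect_false(f$provenance$source_crew[1] == f$provenance$source_crew[2])
    expect_identical(ncol(f$rec1$samples), ncol(f$rec2$samples))
  }
  fakes2 <- make_fake_crews(sims, n_fake = 6, seed = 9)
  expect_identical(lapply(fakes, `[[`, "provenance"),
                   lapply(fakes2, `[[`, "provenance"))
  expect_error(make_fake_crews(sims[1], n_fake = 2), ">= 2")
})

test_that("group comparison gates on normality and reports effect sizes", {
  set.seed(90)
  a <- rnorm(20)
  b <- rnorm(20, 3)
  res <- compare_groups(a, b)
  expect_identical(res$test, "unpaired t-test")
  expect_lt(res$p, 0.001)
  expect_lt(res$effect_size, -2) # Cohen's d, a below b
  # heavy skew selects the rank test
  skew <- exp(rnorm(20, 0, 1.5))
  res2 <- compare_groups(skew, rnorm(20, 3))
  expect_identical(res2$test, "Mann-Whitney")
  # identical groups: non-significant
  same <- rnorm(15)
  expect_gt(compare_groups(same, same, paired = FALSE)$p, 0.9)
  # constant group falls back to the rank test with a warning
  expect_warning(res3 <- compare_groups(rep(1, 5), rnorm(5)), "constant group")
  expect_identical(res3$test, "Mann-Whitney")
  expect_error(compare_groups(1:2, 1:5), "3")
})

test_that("rating correlation reproduces brute-force Pearson on aligned windows", {
  idx <- feature_series(values = seq(0.1, 4, length.out = 40), window_s = 10,
                        start_times = (0:39) * 10, kind = "CCI")
  ratings <- data.frame(window_start_s = (0:9) * 30)
  agg <- sapply(ratings$window_start_s, function(t0)
    mean(idx$values[idx$start_times >= t0 & idx$start_times + 10 <= t0 + 30]))
  set.seed(91)
  ratings$rating <- 2 * agg + rnorm(10, 0, 0.5)
  rc <- rating_correlation(idx, ratings)
  expect_equal(rc$r, cor(agg, ratings$rating), tolerance = 1e-12)
  expect_equal(rc$p, cor.test(agg, ratings$rating)$p.value, tolerance = 1e-12)
  # affine map -> r = 1; negation -> r = -1
  ratings$rating <- 3 * agg + 5
  expect_equal(rating_correlation(idx, ratings)$r, 1, tolerance = 1e-9)
  ratings$rating <- -agg
  expect_equal(rating_correlation(idx, ratings)$r, -1, tolerance = 1e-9)
  ratings$rating <- rep(1, 10)
  expect_error(rating_correlation(idx, ratings), "zero-variance")
})

test_that("phase ANOVA reports F, p and omega-squared, plus assumption checks", {
  # textbook-style balanced 3-group layout with known effect
  set.seed(92)
  k <- 8
  df <- data.frame(
    value = c(rnorm(k, 0), rnorm(k, 0), rnorm(k, 2)),
    phase = rep(c("low_diff", "high_diff", "cooperation"), each = k),
    crew = rep(paste0("c", 1:k), 3))
  res <- phase_anova(df$value, df$phase, df$crew)
  fit <- aov(value ~ phase, df)
  tab <- anova(fit)
  expect_equal(res$table$F, tab$`F value`[1], tolerance = 1e-12)
  expect_equal(res$table$p, tab$`Pr(>F)`[1], tolerance = 1e-12)
  # omega^2 against the closed form
  ss <- tab$`Sum Sq`
  ms_err <- tab$`Mean Sq`[2]
  omega <- (ss[1] - tab$Df[1] * ms_err) / (sum(ss) + ms_err)
  expect_equal(res$table$omega_sq, omega, tolerance = 1e-12)
  expect_true(is.finite(res$resid_normality_p))
  expect_true(is.finite(res$homoscedasticity_p))
  # rank alternatives
  expect_identical(res$rank_alternative$test, "Kruskal-Wallis")
  resf <- phase_anova(df$value, df$phase, df$crew, friedman = TRUE)
  expect_identical(resf$rank_alternative$test, "Friedman")
  expect_lt(resf$rank_alternative$p, 0.05)
  # null simulation: identical distributions give unremarkable F
  set.seed(93)
  ps <- replicate(20, {
    v <- rnorm(3 * k)
    phase_anova(v, df$phase, df$crew)$table$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("omega-squared matches a hand calculation on a fixed small table", {
  # three groups of three, chosen for clean sums of squares
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- phase_anova(v, g, rep(paste0("crew", 1:3), 3))
  # by hand: SSb = 54, SSw = 6, dfb = 2, MSw = 1, omega^2 = (54-2)/(60+1)
  expect_equal(res$table$omega_sq, 52 / 61, tolerance = 1e-12)
  expect_equal(res$table$F, 27, tolerance = 1e-12)
})
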