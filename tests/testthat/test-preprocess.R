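test_that("CSV round-trips preserve the sample matrix in both layouts", {
  sim <- simulate_dyad(quick_scenario(seed = 2, phase_s = 5, noise = 1))
  rec <- sim$session$rec1
  for (fmt in c("wide", "long")) {
    path <- tempfile(fileext = ".csv")
    write_recording_csv(rec, path, format = fmt)
    back <- read_recording_csv(path, operator_id = rec$operator_id)
    expect_equal(back$samples, rec$samples, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(back$fs, rec$fs, tolerance = 1e-9)
    expect_identical(back$channel_labels, rec$channel_labels)
    unlink(path)
  }
})

test_that("reading flags missing required channels and bad files distinctly", {
  sim <- simulate_dyad(quick_scenario(seed = 2, phase_s = 5, noise = 1))
  rec <- exclude_channels(sim$session$rec1, "Pz")
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  expect_error(read_recording_csv(path, channels = c("Pz", "P3")), "Pz")
  expect_error(read_recording_csv(tempfile()), "not found")
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_recording_csv(bad), "time_s")
  unlink(c(path, bad))
})

test_that("channel exclusion removes the named channels, preserves order, guards formulas", {
  sim <- simulate_dyad(quick_scenario(seed = 2, phase_s = 5))
  rec <- sim$session$rec1
  out <- exclude_channels(rec, c("AF7", "AF8"))
  expect_length(out$channel_labels, 6)
  expect_identical(out$channel_labels, setdiff(rec$channel_labels, c("AF7", "AF8")))
  expect_identical(exclude_channels(rec, character(0)), rec)
  expect_error(exclude_channels(rec, "AF3", check_required = TRUE),
               "configuration error")
  expect_error(exclude_channels(rec, "XYZ"), "unknown")
})

test_that("band-pass filter attenuates out-of-band and preserves in-band tones", {
  fs <- 125
  t <- (0:(20 * fs - 1)) / fs
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * t), 1), fs, "AFz")
  spec <- filter_spec() # 2-30 Hz, order 5, zero phase
  mid <- function(x) x[round(length(x) * 0.25):round(length(x) * 0.75)]
  # 1 Hz: >= 20 dB down (amplitude ratio < 0.1)
  y1 <- bandpass_notch(mk(1), spec)$samples[1, ]
  expect_lt(max(abs(mid(y1))), 0.1)
  # 10 Hz: within 5%
  y10 <- bandpass_notch(mk(10), spec)$samples[1, ]
  expect_equal(max(abs(mid(y10))), 1, tolerance = 0.05)
  # DC removed
  ydc <- bandpass_notch(eeg_recording(matrix(5, 1, 10 * fs), fs, "AFz"), spec)
  expect_lt(max(abs(mid(ydc$samples[1, ]))), 1e-3)
  # 50 Hz notch suppresses mains (filter range extended to include 50 Hz)
  y50 <- bandpass_notch(mk(50), filter_spec(lowpass_hz = 55))$samples[1, ]
  expect_lt(max(abs(mid(y50))), 0.1)
  expect_error(bandpass_notch(mk(10), filter_spec(lowpass_hz = 70)), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(9)
  fs <- 125
  x <- rnorm(5 * fs)
  y <- rnorm(5 * fs)
  f <- function(v) bandpass_notch(eeg_recording(matrix(v, 1), fs, "AFz"))$samples[1, ]
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)
})

test_that("epoching conserves samples and masks exactly the over-threshold epochs", {
  fs <- 125
  set.seed(10)
  v <- runif(10 * fs + 37, -50, 50) # non-integer number of epochs
  v[2 * fs + 60] <- 150             # spike inside epoch 3
  rec <- eeg_recording(matrix(v, 1), fs, "AFz")
  ep <- epoch_and_mask(rec, 1, 80)
  expect_identical(dim(ep$epochs)[1], 10L) # partial tail dropped
  expect_identical(dim(ep$epochs)[1] * dim(ep$epochs)[3] + 37L, length(v))
  expect_identical(which(ep$artifact_mask), 3L)
  # all clean -> no artifacts
  ep2 <- epoch_and_mask(eeg_recording(matrix(runif(5 * fs, -50, 50), 1), fs, "AFz"), 1, 80)
  expect_false(any(ep2$artifact_mask))
  expect_error(epoch_and_mask(rec, 0), "positive")
})

test_that("artifact mask is monotone in the threshold", {
  set.seed(12)
  fs <- 125
  v <- rnorm(20 * fs, 0, 40)
  rec <- eeg_recording(matrix(v, 1), fs, "AFz")
  m80 <- epoch_and_mask(rec, 1, 80)$artifact_mask
  m60 <- epoch_and_mask(rec, 1, 60)$artifact_mask
  expect_true(all(m80 <= m60)) # lowering the threshold never unmasks
})

test_that("simulated blinks are masked exactly where the generator injected them", {
  sc <- quick_scenario(seed = 6, phase_s = 20, blink_rate = 6, noise = 2)
  sim <- simulate_dyad(sc)
  ep <- preprocess_recording(sim$session$rec1)
  expect_identical(sort(unique(sim$truth$blinks$epoch)), which(ep$artifact_mask))
  # frontal-only artifacts: parietal-only analysis must see clean epochs
  rec_par <- exclude_channels(sim$session$rec1,
                              c("AFz", "AF3", "AF4", "AF7", "AF8"))
  ep_par <- epoch_and_mask(bandpass_notch(rec_par), 1, 80)
  expect_false(any(ep_par$artifact_mask))
})
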