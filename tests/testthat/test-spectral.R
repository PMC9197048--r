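test_that("the Slepian taper has unit energy and smooth symmetric shape", {
  v <- dpss_taper(500, 1)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  expect_true(all(v > 0))
  expect_equal(v, rev(v), tolerance = 1e-9)
  expect_equal(which.max(v), 250, tolerance = 1)
})

test_that("stationary noise yields a near-zero difference spectrum", {
  set.seed(41)
  ts <- make_trials(n_trials = 80)
  tf <- tf_difference_spectrum(ts)
  # mean |dB| over 10-frequency-bin regions stays inside estimator
  # noise at every well-separated post-onset window (excluding the
  # demeaned near-DC bins)
  sel <- tf$freqs >= 8 & tf$freqs <= 250
  for (tc in c(0.15, 0.4, 0.65)) {
    w <- which.min(abs(tf$time_centers - tc))
    v <- tf$values[w, sel]
    blocks <- split(v, (seq_along(v) - 1) %/% 10)
    expect_true(all(abs(vapply(blocks, mean, numeric(1))) < 1))
  }
})

test_that("a stimulus-locked tone produces a post-onset ridge at its bin", {
  set.seed(42)
  ts <- make_trials(n_trials = 60, amp = 1.5, freq = 50)
  tf <- tf_difference_spectrum(ts)
  post <- tf$time_centers > 0.3 & tf$time_centers < 0.5
  pre <- tf$time_centers < -0.3
  ridge <- colMeans(tf$values[post, , drop = FALSE])
  expect_lte(abs(tf$freqs[which.max(ridge)] - 50), 4)  # within one 4 Hz bin
  expect_gt(max(ridge), 6)
  # the ridge is confined to post-onset windows: pre-onset deviations
  # stay at estimator-noise level, far below the ridge
  sel <- tf$freqs >= 8 & tf$freqs <= 250
  expect_lt(max(abs(colMeans(tf$values[pre, sel, drop = FALSE]))), 3)
  expect_lt(max(abs(colMeans(tf$values[pre, sel, drop = FALSE]))),
            max(ridge) / 2)
})

test_that("doubling the tone amplitude raises the ridge by about 6 dB", {
  set.seed(43)
  n <- 4000; fs <- 2000
  t <- -1 + (0:(n - 1)) / fs
  noise <- one_over_f_noise(n, 30, fs, 1, 0.2)
  env <- as.numeric(t >= 0 & t < 0.8)
  mk <- function(A) {
    lfp <- noise
    for (tr in 1:30)
      lfp[tr, ] <- lfp[tr, ] + A * env * sin(2 * pi * 50 * t +
                                             runif(1, 0, 2 * pi))
    trial_set(lfp, fs, which.min(abs(t)))
  }
  p1 <- change_in_power(mk(1)); p2 <- change_in_power(mk(2))
  k <- which.min(abs(p1$freqs - 50))
  expect_equal(p2$delta_db[k] - p1$delta_db[k], 6, tolerance = 1)
})

test_that("injected power ratios calibrate to their decibel values", {
  set.seed(44)
  n <- 4000; fs <- 2000
  t <- -1 + (0:(n - 1)) / fs
  env <- as.numeric(t >= 0 & t < 0.8)
  base_amp <- 0.5
  for (r in c(4, 10, 100)) {
    lfp <- one_over_f_noise(n, 40, fs, 1, 0.05)
    for (tr in 1:40) {
      phi <- runif(1, 0, 2 * pi)
      # tone present throughout, with its power scaled by r during stimulus
      lfp[tr, ] <- lfp[tr, ] +
        base_amp * (1 + (sqrt(r) - 1) * env) * sin(2 * pi * 50 * t + phi)
    }
    pc <- change_in_power(trial_set(lfp, fs, which.min(abs(t))))
    k <- which.min(abs(pc$freqs - 50))
    expect_equal(pc$delta_db[k], 10 * log10(r), tolerance = 1)
    # tone localized within one 4 Hz-equivalent bin (the difference
    # spectrum is flat across the taper mainlobe, so the argmax may sit
    # at its edge)
    expect_lte(abs(pc$freqs[which.max(pc$delta_db)] - 50), 4)
  }
})

test_that("the cosine-taper fallback agrees with the Slepian within 1 dB", {
  set.seed(45)
  # ratio-calibration construction: the decibel change at the tone bin
  # is a pure power ratio, which any unit-energy taper must reproduce
  n <- 4000; fs <- 2000
  t <- -1 + (0:(n - 1)) / fs
  env <- as.numeric(t >= 0 & t < 0.8)
  lfp <- one_over_f_noise(n, 30, fs, 1, 0.05)
  for (tr in 1:30) {
    phi <- runif(1, 0, 2 * pi)
    lfp[tr, ] <- lfp[tr, ] +
      0.5 * (1 + (sqrt(10) - 1) * env) * sin(2 * pi * 50 * t + phi)
  }
  ts <- trial_set(lfp, fs, which.min(abs(t)))
  a <- change_in_power(ts)
  b <- change_in_power(ts, taper = "cosine")
  k <- which.min(abs(a$freqs - 50))
  expect_equal(a$delta_db[k], 10, tolerance = 1)
  expect_lt(abs(a$delta_db[k] - b$delta_db[k]), 1)
})

test_that("gamma band selection applies the low-contrast 5 Hz shift", {
  expect_equal(select_gamma_band(c(35, 65), 100, 50), c(35, 65))
  expect_equal(select_gamma_band(c(35, 65), 50, 100), c(35, 65))
  expect_equal(select_gamma_band(c(35, 65), 50, 50), c(30, 60))
  expect_equal(select_gamma_band(c(45, 75), 0, 0), c(40, 70))
  expect_error(select_gamma_band(c(35, 65), 120, 50), "contrast")
})

test_that("band power sums inclusive bins and rejects empty bands", {
  freqs <- seq(0, 100, by = 4)
  p <- rep(2, length(freqs))
  expect_equal(band_power(freqs, p, c(36, 64)), 2 * sum(freqs >= 36 &
                                                        freqs <= 64))
  q <- numeric(length(freqs)); q[freqs == 48] <- 7
  expect_equal(band_power(freqs, q, c(35, 65)), 7)
  expect_equal(band_power(freqs, q, c(48, 48)), 7)  # inclusive edges
  expect_error(band_power(freqs, p, c(101, 102)), "band")
})

test_that("normalization maps the maximum to exactly 1 and is idempotent", {
  x <- c(a = 4, b = 2, c = 1)
  n1 <- normalized_band_power(x)
  expect_identical(n1, c(a = 1, b = 0.5, c = 0.25))
  expect_identical(normalized_band_power(n1), n1)
  expect_identical(max(normalized_band_power(runif(7))), 1)
  expect_error(normalized_band_power(c(0, 0)), "positive")
})

test_that("stimulus and baseline analysis windows never overlap", {
  ts <- make_trials(n_trials = 2)
  pc <- change_in_power(ts)
  expect_lte(pc$base_window[2], pc$stim_window[1])
})
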