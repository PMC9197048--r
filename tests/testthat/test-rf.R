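test_that("evoked response is the post-onset dip minus the pre-onset dip", {
  t <- seq(-200, 200, by = 0.5)
  expect_equal(evoked_response(rep(0, length(t)), t), 0)
  x <- rep(0, length(t))
  x[t >= -80 & t <= -70] <- -5
  x[t >= 60 & t <= 80] <- -50
  expect_equal(evoked_response(x, t), -45)
  expect_error(evoked_response(x[t > -50], t[t > -50]), "cover")
})

test_that("noiseless Gaussian grids are recovered exactly", {
  g <- generate_rf_grid(center = c(0.27, -0.31), sigmas = c(0.2, 0.3),
                        amplitude = 2, noise_sd = 0)
  est <- fit_rf(g$grid)
  expect_true(est$converged)
  expect_lt(max(abs(est$center - c(0.27, -0.31))), 1e-6)
  expect_equal(unname(est$sigmas), c(0.2, 0.3), tolerance = 1e-6)
  expect_equal(est$size, sqrt(0.2 * 0.3), tolerance = 1e-6)
  expect_false(est$extrapolated)
})

test_that("isotropic truth yields equal fitted SDs", {
  g <- generate_rf_grid(center = c(-0.1, 0.15), sigmas = c(0.25, 0.25),
                        noise_sd = 0)
  est <- fit_rf(g$grid)
  expect_equal(unname(est$sigmas[1]), unname(est$sigmas[2]),
               tolerance = 1e-6)
})

test_that("noisy grids at SNR 5 recover the center within 0.05 degrees", {
  hits <- 0; n_rep <- 40
  for (s in seq_len(n_rep)) {
    g <- generate_rf_grid(center = c(0.1, -0.1), sigmas = c(0.25, 0.25),
                          amplitude = 1, noise_sd = 0.2, seed = 1000 + s)
    est <- fit_rf(g$grid)
    if (est$converged &&
        sqrt(sum((est$center - c(0.1, -0.1))^2)) < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("center-site selection is inclusive and monotone in radius", {
  centers <- data.frame(azimuth = c(0.1, 0.25, 0.0, 0.2),
                        elevation = c(0, 0, 0.15, 0.0))
  sel <- select_center_sites(centers, c(0, 0), 0.2)
  expect_true(1 %in% sel)            # distance 0.1
  expect_false(2 %in% sel)           # distance 0.25
  expect_true(4 %in% sel)            # distance exactly 0.2: inclusive
  for (r in c(0.05, 0.1, 0.15, 0.2, 0.3)) {
    s1 <- select_center_sites(centers, c(0, 0), r)
    s2 <- select_center_sites(centers, c(0, 0), r + 0.05)
    expect_true(all(s1 %in% s2))
  }
})
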