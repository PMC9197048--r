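test_that("identical config and seed give identical sessions", {
  cfg <- session_config(n_trials = 4, n_units = 3, seed = 99)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$trials[[1]]$lfp, b$trials[[1]]$lfp)
  expect_identical(a$spikes$units, b$spikes$units)
  c2 <- generate_session(session_config(n_trials = 4, n_units = 3,
                                        seed = 100))
  expect_false(identical(a$trials[[1]]$lfp, c2$trials[[1]]$lfp))
})

test_that("programmed attenuation and frequency laws are stored exactly", {
  cfg <- session_config(n_trials = 2, n_units = 2)
  s <- generate_session(cfg)
  expect_equal(s$truth$amplitude[5] / s$truth$amplitude[1],
               exp(-0.2 / 0.1), tolerance = 1e-12)
  expect_equal(s$truth$frequency, 50 + 20 * c(0, 0.025, 0.05, 0.1, 0.2))
  # degenerate no-attenuation case: equal programmed amplitude everywhere
  s2 <- generate_session(session_config(n_trials = 12, n_units = 2,
                                        attenuation_lambda = Inf,
                                        seed = 3))
  expect_true(all(s2$truth$amplitude == s2$truth$amplitude[1]))
  an <- analyze_session(s2)
  expect_true(all(an$per_condition$norm_gamma > 0.8))
})

test_that("baseline noise follows the programmed 1/f spectral slope", {
  set.seed(61)
  x <- one_over_f_noise(8192, 30, 2000, beta = 1)
  ps <- 0
  for (tr in 1:30) {
    p <- taper_psd(x[tr, ], 2000, taper = "cosine")
    ps <- ps + p$power
  }
  f <- p$freqs
  sel <- f >= 5 & f <= 200
  slope <- ols_slope_closed_form(log10(f[sel]), log10(ps[sel] / 30))
  expect_equal(-slope, 1, tolerance = 0.1)
})

test_that("spike counts match the programmed rates within Poisson error", {
  cfg <- session_config(n_trials = 100, n_units = 4, unit_sdlog = 0,
                        seed = 7)
  s <- generate_session(cfg)
  for (u in 1:4) for (cc in c(1, 5)) {
    counts <- vapply(s$spikes$units[[u]][[cc]], function(st)
      sum(st >= 0 & st <= 0.8), numeric(1))
    lam <- s$truth$rates[u, cc] * 0.8
    # mean of 100 Poisson(lam) draws within 4 standard errors
    expect_lt(abs(mean(counts) - lam), 4 * sqrt(lam / 100))
  }
})

test_that("spike containers respect trial bounds and ordering", {
  s <- generate_session(session_config(n_trials = 5, n_units = 3))
  for (u in s$spikes$units) for (cond in u) for (st in cond) {
    if (length(st)) {
      expect_false(is.unsorted(st))
      expect_gte(min(st), -1)
      expect_lte(max(st), 1)
    }
  }
})

test_that("model-driven generation with a constant mapping is flat", {
  md <- generate_model_driven_session(ei_model_spec(), rep(1, 5),
                                      session_config(n_trials = 10,
                                                     n_units = 2,
                                                     seed = 17))
  an <- analyze_session(md)
  expect_true(all(an$per_condition$norm_gamma > 0.85))
  expect_error(
    generate_model_driven_session(ei_model_spec(), c(1, 0.8, 0.9, 0.7, 0.6),
                                  session_config()),
    "non-increasing")
})
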