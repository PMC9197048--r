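make_unit <- function(rates, n_trials = 10, stim = c(0.25, 0.75)) {
  # deterministic regular spike trains at the requested stimulus rates;
  # rate * window must be a whole number of spikes
  lapply(rates, function(r) {
    count <- round(r * diff(stim))
    lapply(seq_len(n_trials), function(tr) {
      if (count <= 0) return(numeric(0))
      stim[1] + (seq_len(count) - 1) * diff(stim) / count
    })
  })
}

test_that("unit selection keeps the 1 spike/s boundary inclusive", {
  # exactly 1.0 spikes/s mean in-window rate: 1 spike in half the trials
  boundary <- list(lapply(1:10, function(tr)
    if (tr <= 5) 0.5 else numeric(0)),
    lapply(1:10, function(tr) numeric(0)))
  units <- list(
    silent = make_unit(c(0, 0)),
    boundary = boundary,
    active = make_unit(c(10, 5)))
  ss <- spike_set(units, data.frame(label = c("a", "b"),
                                    magnitude = c(0, 0.1)))
  expect_identical(select_spiking_units(ss), c("boundary", "active"))
})

test_that("scalar tuning normalizes per unit to a maximum of 1", {
  ss <- spike_set(list(u1 = make_unit(c(8, 4)),
                       u2 = make_unit(c(4, 8))),
                  data.frame(label = c("a", "b"), magnitude = c(0, 0.1)))
  nr <- normalized_rates(ss)
  expect_equal(unname(nr$tuning["u1", ]), c(1, 0.5))
  expect_equal(unname(nr$tuning["u2", ]), c(0.5, 1))
  # time courses max-normalized per unit
  expect_equal(max(nr$timecourses$u1), 1)
  # the alternative convention also peaks at 1
  nr2 <- normalized_rates(ss, scalar = "timecourse_max")
  expect_equal(unname(apply(nr2$tuning, 1, max)), c(1, 1))
})

test_that("OLS slope equals the closed-form ratio and exact fits recover", {
  x <- c(0, 0.1, 0.2)
  r <- discontinuity_regression(1 - 2 * x, x)
  expect_equal(r$slope, -2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  r0 <- discontinuity_regression(rep(0.7, 4), c(0, 1, 2, 3))
  expect_equal(r0$slope, 0, tolerance = 1e-14)
  set.seed(51)
  for (k in 1:20) {
    x <- sort(runif(5 + k %% 4)); x <- x + seq_along(x) * 1e-6
    y <- rnorm(length(x))
    expect_equal(discontinuity_regression(y, x)$slope,
                 ols_slope_closed_form(x, y), tolerance = 1e-12)
  }
  expect_error(discontinuity_regression(c(1, 2), c(0, 1)), "3 points")
  expect_error(discontinuity_regression(c(1, 2, 3), c(0, 1, 1)),
               "increasing")
})

test_that("the exponential attenuation profile regresses negative", {
  d <- c(0, 0.025, 0.05, 0.1, 0.2)
  v <- exp(-d / 0.1); v <- v / max(v)
  r <- discontinuity_regression(v, d)
  expect_equal(r$slope, ols_slope_closed_form(d, v), tolerance = 1e-10)
  expect_lt(r$slope, 0)
})

test_that("two-sided regression averages the per-side slope magnitudes", {
  x <- seq(-50, 50, by = 10)
  tent <- 1 - abs(x) / 50
  ts <- two_sided_regression(tent, x)
  expect_equal(ts$slope_neg, -1 / 50, tolerance = 1e-12)
  expect_equal(ts$slope_pos, -1 / 50, tolerance = 1e-12)
  expect_equal(ts$mean_abs_slope, 1 / 50, tolerance = 1e-12)
  flat <- two_sided_regression(rep(1, length(x)), x)
  expect_equal(flat$mean_abs_slope, 0, tolerance = 1e-14)
  # subrange restriction drops the far conditions
  ts2 <- two_sided_regression(tent, x, range = 20)
  expect_equal(ts2$n_pos, 3L)
  expect_error(two_sided_regression(tent[x >= 0], x[x >= 0] + 10), "side")
})

test_that("signed-rank p-values match exact enumeration for small n", {
  # all-positive differences, n = 6: two-sided exact p = 1/32
  a <- c(2, 3, 5, 7, 11, 13); b <- a - seq(0.1, 0.6, by = 0.1)
  pc <- paired_comparison(a, b)
  expect_equal(pc$p_value, 1 / 32, tolerance = 1e-12)
  expect_equal(signed_rank_exact_p(a - b), 1 / 32, tolerance = 1e-12)
  set.seed(52)
  for (n in c(5, 7, 10)) for (k in 1:5) {
    d <- round(rnorm(n), 2)
    d[d == 0] <- 0.01
    d <- d + seq_along(d) * 1e-4      # break ties in |d|
    pc <- paired_comparison(d + 10, rep(10, n))
    expect_equal(pc$p_value, signed_rank_exact_p(d), tolerance = 1e-10,
                 info = sprintf("n=%d rep=%d", n, k))
  }
})

test_that("paired comparisons handle degenerate and swapped inputs", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- paired_comparison(x, x)
  expect_true(same$all_zero)
  expect_equal(same$p_value, 1)
  a <- x + c(0.3, -0.1, 0.25, 0.4, -0.2, 0.5)
  f <- paired_comparison(a, x); g <- paired_comparison(x, a)
  expect_equal(f$statistic, -g$statistic, tolerance = 1e-12)
  expect_equal(f$p_value, g$p_value, tolerance = 1e-12)
  t1 <- paired_comparison(a, x, test = "t_two_sided")
  expect_equal(t1$p_value, t.test(a, x, paired = TRUE)$p.value)
})
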