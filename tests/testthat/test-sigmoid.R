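test_that("sigmoid response passes through zero and its symmetry point", {
  for (p in list(population_params(1, 5), population_params(2, 3),
                 population_params(0.5, 20))) {
    expect_identical(sigmoid_response(0, p), 0)
    expect_equal(sigmoid_response(p$threshold, p),
                 0.5 - 1 / (1 + exp(p$gain * p$threshold)))
  }
  # closed-form spot value, m = 1, theta = 5, drive = 10
  expect_equal(sigmoid_response(10, population_params(1, 5)),
               1 / (1 + exp(-5)) - 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(round(sigmoid_response(10, population_params(1, 5)), 5),
               0.98661)
})

test_that("sigmoid is strictly increasing with positive derivative", {
  set.seed(11)
  p <- population_params(1, 5)
  x <- sort(runif(100, -30, 30))
  y <- sigmoid_response(x, p)
  expect_true(all(diff(y) > 0))
  # analytical derivative against central finite differences
  h <- 1e-6
  fd <- (sigmoid_response(x + h, p) - sigmoid_response(x - h, p)) / (2 * h)
  expect_equal(sigmoid_slope(x, p), fd, tolerance = 1e-6)
  expect_true(all(sigmoid_slope(x, p) > 0))
})

test_that("sigmoid curvature changes sign exactly at threshold", {
  p <- population_params(1, 20)
  expect_equal(sigmoid_curvature(20, p), 0, tolerance = 1e-15)
  expect_gt(sigmoid_curvature(15, p), 0)
  expect_lt(sigmoid_curvature(25, p), 0)
})

test_that("inverse sigmoid round-trips and rejects saturated values", {
  p <- population_params(1, 5)
  x <- seq(-10, 20, by = 0.5)
  expect_equal(sigmoid_inverse(sigmoid_response(x, p), p), x,
               tolerance = 1e-9)
  r <- sigmoid_range(p)
  expect_error(sigmoid_inverse(r[2], p), "range")
  expect_error(sigmoid_inverse(r[1] - 1e-3, p), "range")
})

test_that("non-finite drive and invalid parameters are rejected", {
  p <- population_params(1, 5)
  expect_error(sigmoid_response(NaN, p), "finite")
  expect_error(sigmoid_response(Inf, p), "finite")
  expect_error(population_params(0, 5), "gain")
  expect_error(population_params(1, -1), "threshold")
})
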