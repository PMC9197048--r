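test_that("regime flags follow the sigmoid curvature at the fixed point", {
  rl <- classify_regime(ei_model_spec(), 3, 7.5)
  expect_true(rl$oscillatory)
  expect_true(rl$e_sublinear)     # E drive above thetaE = 5
  expect_true(rl$i_superlinear)   # I drive below thetaI = 20
  expect_gt(rl$drives[["E"]], 5)
  expect_lt(rl$drives[["I"]], 20)
})

test_that("a far-saturated input is non-oscillatory", {
  rl <- classify_regime(ei_model_spec(), 100, 100, duration_ms = 2000)
  expect_false(rl$oscillatory)
})

test_that("curvature flags are strict at the inflection point", {
  p <- population_params(1, 5)
  expect_false(sigmoid_curvature(5, p) < 0)
  expect_false(sigmoid_curvature(5, p) > 0)
})

test_that("a trivial 1x1 map at the origin is an all-zero cell", {
  m <- input_plane_map(ei_model_spec(), 0, 0, duration_ms = 1600,
                       transient_ms = 500)
  expect_equal(m$E_map[1, 1], 0)
  expect_equal(m$I_map[1, 1], 0)
  expect_equal(m$amp_map[1, 1], 0)
  expect_false(m$sustained[1, 1])
})

test_that("unperturbed entry of the perturbation experiment is the identity", {
  res <- weight_perturbation_experiment(ei_model_spec(), "wee", 1,
                                        iE = 3, iI = 7.5,
                                        duration_ms = 2500)
  expect_equal(res$scale, 1)
  expect_equal(res$fixed_point_shift, 0, tolerance = 1e-10)
  expect_true(res$sustained)
})

test_that("weakening recurrent excitation collapses the oscillation", {
  res <- weight_perturbation_experiment(ei_model_spec(), "wee",
                                        c(1, 0.9, 0.8), iE = 3, iI = 7.5)
  expect_true(all(diff(res$peak_power) < 0))       # strictly decreasing
  expect_lt(res$peak_power[3] / res$peak_power[1], 0.1)
  rel_drop <- 1 - res$peak_power[3] / res$peak_power[1]
  expect_lt(res$fixed_point_shift[3], rel_drop / 5)
})
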