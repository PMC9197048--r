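test_that("origin is a fixed point under zero input", {
  tr <- simulate_ei(ei_model_spec(), 0, 0, duration_ms = 500)
  expect_true(all(abs(tr$E) < 1e-12))
  expect_true(all(abs(tr$I) < 1e-12))
})

test_that("default operating point yields a sustained gamma-band cycle", {
  tr <- simulate_ei(ei_model_spec(), 3, 7.5, duration_ms = 3000)
  om <- oscillation_metrics(tr, transient_ms = 1000)
  expect_true(om$sustained)
  expect_gt(om$peak_frequency, 20)
  expect_lt(om$peak_frequency, 100)
})

test_that("trajectories stay inside the sigmoid ranges", {
  set.seed(21)
  spec <- ei_model_spec()
  rE <- sigmoid_range(spec$e_params); rI <- sigmoid_range(spec$i_params)
  for (k in 1:8) {
    sp <- random_spec()
    tr <- simulate_ei(sp, runif(1, 0, 10), runif(1, 0, 20),
                      duration_ms = 1000)
    expect_true(all(tr$E >= rE[1] - 1e-9 & tr$E <= rE[2] + 1e-9))
    expect_true(all(tr$I >= rI[1] - 1e-9 & tr$I <= rI[2] + 1e-9))
  }
})

test_that("fixed-step solution matches an adaptive reference integrator", {
  spec <- ei_model_spec()
  ref <- desolve_reference(spec, 2, 10, 1000)   # damped regime
  tr <- simulate_ei(spec, 2, 10, duration_ms = 1000)
  at <- match(ref$time, tr$times)
  expect_equal(tr$E[at], ref$E, tolerance = 1e-7)
  expect_equal(tr$I[at], ref$I, tolerance = 1e-7)
})

test_that("halving the step leaves the late trajectory unchanged", {
  spec <- ei_model_spec()
  a <- simulate_ei(spec, 3, 7.5, duration_ms = 2000, dt_ms = 0.05)
  b <- simulate_ei(spec, 3, 7.5, duration_ms = 2000, dt_ms = 0.025)
  ia <- a$times >= 1000
  expect_lt(max(abs(a$E[ia] - b$E[seq(1, length(b$E), 2)][ia])), 1e-4)
})

test_that("preconditions and the noise hook behave as documented", {
  spec <- ei_model_spec()
  expect_error(simulate_ei(spec, 3, 7.5, dt_ms = 0.5), "dt_ms")
  expect_error(simulate_ei(spec, 3, 7.5, duration_ms = 100), "duration")
  expect_error(simulate_ei(spec, 3, 7.5, init = c(2, 0)), "initial state")
  # noise off by default: two runs identical
  a <- simulate_ei(spec, 3, 7.5, duration_ms = 300)
  b <- simulate_ei(spec, 3, 7.5, duration_ms = 300)
  expect_identical(a$E, b$E)
  # noise on: seeded determinism through the RNG
  set.seed(5); c1 <- simulate_ei(spec, 3, 7.5, duration_ms = 300,
                                 noise_sd = 0.1)
  set.seed(5); c2 <- simulate_ei(spec, 3, 7.5, duration_ms = 300,
                                 noise_sd = 0.1)
  expect_identical(c1$E, c2$E)
  expect_false(identical(a$E, c1$E))
})
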