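test_that("both nullclines pass through the origin at zero input", {
  nc <- nullclines(ei_model_spec(), 0, 0,
                   e_grid = seq(-0.005, 0.05, by = 0.005))
  j <- which(nc$e_nullcline$E == 0)
  expect_length(j, 1L)
  expect_lt(abs(nc$e_nullcline$I[j]), 1e-9)
  expect_lt(abs(nc$i_nullcline$I[j]), 1e-9)
})

test_that("sampled nullcline points satisfy their defining equations", {
  spec <- ei_model_spec()
  w <- effective_weights(spec)
  nc <- nullclines(spec, 3, 7.5)
  resE <- -nc$e_nullcline$E +
    sigmoid_response(w$wee * nc$e_nullcline$E - w$wei * nc$e_nullcline$I + 3,
                     spec$e_params)
  resI <- -nc$i_nullcline$I +
    sigmoid_response(w$wie * nc$i_nullcline$E - w$wii * nc$i_nullcline$I + 7.5,
                     spec$i_params)
  expect_lt(max(abs(resE)), 1e-9)
  expect_lt(max(abs(resI)), 1e-9)
})

test_that("perturbing wee moves only the E-nullcline (and wii only the I)", {
  spec <- ei_model_spec()
  eg <- seq(-0.005, 0.99, length.out = 200)
  nc0 <- nullclines(spec, 3, 7.5, e_grid = eg)
  for (sc in c(0.9, 0.8)) {
    ncw <- nullclines(apply_discontinuity(spec, "wee", sc), 3, 7.5,
                      e_grid = eg)
    expect_identical(ncw$i_nullcline$I, nc0$i_nullcline$I)
    expect_gt(max(abs(ncw$e_nullcline$I - nc0$e_nullcline$I)), 1e-3)
    # symmetric check: wii leaves the E-nullcline untouched
    ncv <- nullclines(apply_discontinuity(spec, "wii", sc), 3, 7.5,
                      e_grid = eg)
    expect_identical(ncv$e_nullcline$I, nc0$e_nullcline$I)
    expect_gt(max(abs(ncv$i_nullcline$I - nc0$i_nullcline$I)), 1e-6)
  }
})

test_that("nullcline intersections coincide with the fixed points", {
  spec <- ei_model_spec()
  for (inp in list(c(3, 7.5), c(1, 2), c(5, 12))) {
    fps <- find_fixed_points(spec, inp[1], inp[2])
    eg <- sort(unique(c(seq(-0.006, 0.99, length.out = 2000), fps$E)))
    nc <- nullclines(spec, inp[1], inp[2], e_grid = eg)
    # at each fixed point's E, the two curves must (both) pass through I*
    for (r in seq_len(nrow(fps))) {
      j <- which.min(abs(nc$e_nullcline$E - fps$E[r]))
      expect_lt(abs(nc$e_nullcline$I[j] - fps$I[r]), 1e-6)
      expect_lt(abs(nc$i_nullcline$I[j] - fps$I[r]), 1e-6)
    }
  }
})
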