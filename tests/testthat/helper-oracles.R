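# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of
# all 2^n sign assignments (n <= ~15 is practical).
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  # distribution of V over all sign assignments
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  # two-sided: as extreme or more, in |V - mu|
  mean(abs(Vs - mu) >= abs(V - mu) - 1e-12)
}

# Closed-form OLS slope (covariance over variance).
ols_slope_closed_form <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Reference E-I simulation via deSolve (adaptive LSODA), independent of
# the package's fixed-step integrator.
desolve_reference <- function(spec, iE, iI, duration_ms, init = c(0, 0),
                              out_dt = 1) {
  w <- effective_weights(spec)
  sig <- function(x, m, th) 1 / (1 + exp(-m * (x - th))) - 1 / (1 + exp(m * th))
  deriv <- function(t, y, p) {
    list(c(
      (-y[1] + sig(w$wee * y[1] - w$wei * y[2] + iE,
                   spec$e_params$gain, spec$e_params$threshold)) /
        spec$taus[["tauE"]],
      (-y[2] + sig(w$wie * y[1] - w$wii * y[2] + iI,
                   spec$i_params$gain, spec$i_params$threshold)) /
        spec$taus[["tauI"]]))
  }
  out <- deSolve::ode(y = init, times = seq(0, duration_ms, by = out_dt),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  data.frame(time = out[, 1], E = out[, 2], I = out[, 3])
}

# Random model spec with bounded weights and default sigmoids/taus.
random_spec <- function() {
  ei_model_spec(gains = connection_gains(
    Wee = runif(1, 5, 25), Wei = runif(1, 5, 30),
    Wie = runif(1, 5, 30), Wii = runif(1, 0, 5)))
}

# Small synthetic trial matrix: stationary 1/f noise with an optional
# stimulus-epoch sinusoid, for spectral calibration tests.
make_trials <- function(n_trials = 30, amp = 0, freq = 50, fs = 2000,
                        t_range = c(-1, 1), beta = 1, scale = 1,
                        stim = c(0, 0.8)) {
  n <- round(diff(t_range) * fs)
  t <- t_range[1] + (seq_len(n) - 1) / fs
  lfp <- one_over_f_noise(n, n_trials, fs, beta, scale)
  if (amp > 0) {
    env <- as.numeric(t >= stim[1] & t < stim[2])
    for (tr in seq_len(n_trials))
      lfp[tr, ] <- lfp[tr, ] + amp * env * sin(2 * pi * freq * t +
                                               runif(1, 0, 2 * pi))
  }
  trial_set(lfp, fs, which.min(abs(t)))
}
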