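#' Simulate the E-I network
#'
#' Deterministic fixed-step classical RK4 integration of the two coupled
#' rate equations
#' \deqn{\tau_E \dot E = -E + f_E(w_{ee}E - w_{ei}I + i_E),\quad
#'       \tau_I \dot I = -I + f_I(w_{ie}E - w_{ii}I + i_I).}
#' Time is in milliseconds.  An optional additive drive-noise hook is
#' available (`noise_sd > 0`) but is off by default; the reference
#' simulations are noise-free.
#'
#' @param spec An [ei_model_spec()].
#' @param iE,iI External drives to the E and I populations (finite,
#'   non-negative in all standard sweeps).
#' @param duration_ms Total simulated time (ms); must be at least
#'   `10 * tauE`.
#' @param dt_ms Integration step (ms); must satisfy `dt_ms <= tauI / 50`.
#' @param init Initial state `c(E0, I0)`, within the sigmoid ranges.
#' @param noise_sd Standard deviation of white drive noise per
#'   `sqrt(ms)`; 0 disables the hook.
#' @return An object of class `ei_trajectory`: list with `times` (ms),
#'   `E`, `I`, `dt_ms`, and the inputs used.
#' @examples
#' tr <- simulate_ei(ei_model_spec(), iE = 3, iI = 7.5, duration_ms = 1000)
#' range(tr$E)
#' @export
simulate_ei <- function(spec, iE, iI, duration_ms = 2000, dt_ms = 0.05,
                        init = c(0, 0), noise_sd = 0) {
  stopifnot(inherits(spec, "ei_model_spec"),
            is.numeric(iE), length(iE) == 1L, is.finite(iE),
            is.numeric(iI), length(iI) == 1L, is.finite(iI),
            is.numeric(duration_ms), length(duration_ms) == 1L,
            is.numeric(dt_ms), length(dt_ms) == 1L, dt_ms > 0,
            length(init) == 2L, all(is.finite(init)),
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  tauE <- spec$taus[["tauE"]]; tauI <- spec$taus[["tauI"]]
  if (dt_ms > tauI / 50)
    stop("dt_ms too coarse: must be <= tauI/50 = ", tauI / 50, " ms")
  if (duration_ms < 10 * tauE)
    stop("duration_ms must be >= 10 * tauE = ", 10 * tauE, " ms")
  rE <- sigmoid_range(spec$e_params); rI <- sigmoid_range(spec$i_params)
  if (init[1] < rE[1] || init[1] > rE[2] || init[2] < rI[1] || init[2] > rI[2])
    stop("initial state outside the sigmoid range")

  w <- effective_weights(spec)
  n <- as.integer(round(duration_ms / dt_ms))
  if (noise_sd > 0) {
    sd_step <- noise_sd / sqrt(dt_ms)
    noiseE <- stats::rnorm(n, 0, sd_step)
    noiseI <- stats::rnorm(n, 0, sd_step)
  } else {
    noiseE <- numeric(0); noiseI <- numeric(0)
  }
  out <- rk4_ei_core(w$wee, w$wei, w$wie, w$wii,
                     spec$e_params$gain, spec$e_params$threshold,
                     spec$i_params$gain, spec$i_params$threshold,
                     tauE, tauI, iE, iI, n, dt_ms,
                     init[1], init[2], noiseE, noiseI)
  if (!out$ok)
    stop("numerical blow-up: state became non-finite at t = ",
         format(out$n_done * dt_ms), " ms (wee=", format(w$wee),
         ", iE=", format(iE), ", iI=", format(iI), ")")
  structure(list(times = seq(0, n) * dt_ms, E = out$E, I = out$I,
                 dt_ms = dt_ms, iE = iE, iI = iI, spec = spec),
            class = "ei_trajectory")
}

#' @export
print.ei_trajectory <- function(x, ...) {
  cat(sprintf(
    "E-I trajectory: %d samples, dt = %g ms, duration = %g ms (iE=%g, iI=%g)\n",
    length(x$times), x$dt_ms, max(x$times), x$iE, x$iI))
  cat(sprintf("  final state: E = %.6g, I = %.6g\n",
              x$E[length(x$E)], x$I[length(x$I)]))
  invisible(x)
}
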