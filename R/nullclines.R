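#' Nullclines of the E-I network in the (E, I) plane
#'
#' The E-nullcline is solved in closed form as `I(E)` from
#' `E = fE(wee*E - wei*I + iE)` using the inverse sigmoid; the
#' I-nullcline is the curve `I = fI(wie*E - wii*I + iI)`, obtained by a
#' one-dimensional root solve in `I` for each `E` (the right-hand side is
#' strictly decreasing in `I`, so the root is unique).  Grid values at or
#' beyond sigmoid saturation are skipped with a message.
#'
#' @param spec An [ei_model_spec()].
#' @param iE,iI External inputs.
#' @param e_grid E values at which to evaluate both curves; default 400
#'   points strictly inside the E sigmoid range.
#' @return List of class `nullcline_set` with data.frames `e_nullcline`
#'   and `i_nullcline` (columns `E`, `I`), each point satisfying its
#'   steady-state equation to better than 1e-9.
#' @examples
#' nc <- nullclines(ei_model_spec(), iE = 3, iI = 7.5)
#' head(nc$e_nullcline)
#' @export
nullclines <- function(spec, iE, iI, e_grid = NULL) {
  stopifnot(inherits(spec, "ei_model_spec"), is.finite(iE), is.finite(iI))
  w <- effective_weights(spec)
  rE <- sigmoid_range(spec$e_params); rI <- sigmoid_range(spec$i_params)
  if (is.null(e_grid)) {
    pad <- 1e-6
    e_grid <- seq(rE[1] + pad, rE[2] - pad, length.out = 400)
  }
  inside <- e_grid > rE[1] & e_grid < rE[2]
  if (any(!inside))
    message(sum(!inside), " grid value(s) at/beyond sigmoid saturation skipped")
  eg <- e_grid[inside]

  # E-nullcline, closed form
  In_e <- (w$wee * eg + iE - sigmoid_inverse(eg, spec$e_params)) / w$wei

  # I-nullcline, root solve in I per E value
  In_i <- vapply(eg, function(E) {
    f <- function(I) -I + sigmoid_response(w$wie * E - w$wii * I + iI,
                                           spec$i_params)
    stats::uniroot(f, lower = rI[1] - 0.5, upper = rI[2] + 0.5,
                   tol = 1e-13)$root
  }, numeric(1))

  structure(list(
    e_nullcline = data.frame(E = eg, I = In_e),
    i_nullcline = data.frame(E = eg, I = In_i),
    iE = iE, iI = iI), class = "nullcline_set")
}

#' Classify the operating regime at an input point
#'
#' Local-curvature regime criterion at the (unique) fixed point: the E
#' response is sublinear when the E sigmoid's second derivative at the
#' fixed-point drive is negative (drive above threshold), the I response
#' superlinear when the I sigmoid's curvature there is positive (drive
#' below threshold).  `oscillatory` is determined empirically by
#' simulation (sustained limit cycle per [oscillation_metrics()]).
#'
#' @param spec An [ei_model_spec()].
#' @param iE,iI External inputs.
#' @param duration_ms,dt_ms,transient_ms Simulation settings for the
#'   oscillation test.
#' @return List of class `regime_label`: flags `oscillatory`,
#'   `e_sublinear`, `i_superlinear`, plus the fixed point and the drives.
#'   Errors if the fixed point is not unique (classification ambiguous).
#' @export
classify_regime <- function(spec, iE, iI, duration_ms = 3000, dt_ms = 0.05,
                            transient_ms = 1000) {
  fps <- find_fixed_points(spec, iE, iI)
  if (nrow(fps) != 1L)
    stop("regime classification ambiguous: ", nrow(fps),
         " fixed points found (expected exactly 1)")
  w <- effective_weights(spec)
  driveE <- w$wee * fps$E - w$wei * fps$I + iE
  driveI <- w$wie * fps$E - w$wii * fps$I + iI
  tr <- simulate_ei(spec, iE, iI, duration_ms = duration_ms, dt_ms = dt_ms)
  om <- oscillation_metrics(tr, transient_ms = transient_ms)
  structure(list(
    oscillatory = om$sustained,
    e_sublinear = sigmoid_curvature(driveE, spec$e_params) < 0,
    i_superlinear = sigmoid_curvature(driveI, spec$i_params) > 0,
    fixed_point = c(E = fps$E, I = fps$I),
    drives = c(E = driveE, I = driveI)), class = "regime_label")
}
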