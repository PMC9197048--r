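#' Evoked response of a trial-averaged LFP
#'
#' Depth of the early stimulus-evoked deflection: the minimum LFP value
#' between 40 and 100 ms after onset minus the minimum between -100 and
#' -40 ms before onset.  Signed; more negative means a stronger evoked
#' response.
#'
#' @param trial_avg_lfp Trial-averaged LFP samples.
#' @param times_ms Sample times in ms relative to stimulus onset; must
#'   cover \[-100, 100\] ms.
#' @return Scalar evoked response.
#' @export
evoked_response <- function(trial_avg_lfp, times_ms) {
  stopifnot(length(trial_avg_lfp) == length(times_ms))
  if (min(times_ms) > -100 || max(times_ms) < 100)
    stop("series must cover [-100, 100] ms around onset")
  post <- times_ms >= 40 & times_ms <= 100
  pre <- times_ms >= -100 & times_ms <= -40
  min(trial_avg_lfp[post]) - min(trial_avg_lfp[pre])
}

#' Fit a 2D Gaussian receptive field to a response grid
#'
#' Axis-aligned 2D Gaussian (baseline + amplitude *
#' exp(-((az-x0)^2/(2*sd_az^2) + (el-y0)^2/(2*sd_el^2)))) fitted to the
#' magnitude of the evoked responses by nonlinear least squares
#' (Levenberg-Marquardt), with moment-based initialization.  The RF size
#' summary is the geometric mean of the two SDs.
#'
#' @param grid data.frame with columns `azimuth`, `elevation` (degrees)
#'   and `response`; at least 9 finite points.
#' @return Object of class `rf_estimate`: `center` (azimuth, elevation),
#'   `sigmas` (sd_az, sd_el), `amplitude`, `baseline`, `size` (degrees),
#'   `converged`, `extrapolated` (center outside the grid's bounding
#'   box), and `fit` diagnostics.
#' @export
fit_rf <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("azimuth", "elevation", "response") %in% names(grid)))
  grid <- grid[is.finite(grid$response), ]
  if (nrow(grid) < 9) stop("need at least 9 grid points with finite responses")
  az <- grid$azimuth; el <- grid$elevation
  r <- abs(grid$response)

  w <- pmax(r - min(r), 0)
  if (sum(w) == 0) w <- rep(1, length(r))
  x0 <- sum(w * az) / sum(w); y0 <- sum(w * el) / sum(w)
  sa <- sqrt(sum(w * (az - x0)^2) / sum(w))
  se <- sqrt(sum(w * (el - y0)^2) / sum(w))
  span_a <- diff(range(az)); span_e <- diff(range(el))
  sa <- min(max(sa, 0.05 * span_a), span_a)
  se <- min(max(se, 0.05 * span_e), span_e)

  df <- data.frame(az = az, el = el, r = r)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ base + amp * exp(-((az - x0)^2 / (2 * sa^2) +
                             (el - y0)^2 / (2 * se^2))),
      data = df,
      start = list(base = min(r), amp = max(r) - min(r),
                   x0 = x0, y0 = y0, sa = sa, se = se),
      lower = c(base = -Inf, amp = 0, x0 = -Inf, y0 = -Inf,
                sa = 1e-4, se = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(center = c(azimuth = x0, elevation = y0),
                          sigmas = c(sd_az = sa, sd_el = se),
                          amplitude = max(r) - min(r), baseline = min(r),
                          size = sqrt(sa * se), converged = FALSE,
                          extrapolated = NA, fit = NULL),
                     class = "rf_estimate"))
  }
  cf <- stats::coef(fit)
  extrap <- cf[["x0"]] < min(az) || cf[["x0"]] > max(az) ||
            cf[["y0"]] < min(el) || cf[["y0"]] > max(el)
  structure(list(center = c(azimuth = cf[["x0"]], elevation = cf[["y0"]]),
                 sigmas = c(sd_az = cf[["sa"]], sd_el = cf[["se"]]),
                 amplitude = cf[["amp"]], baseline = cf[["base"]],
                 size = sqrt(cf[["sa"]] * cf[["se"]]),
                 converged = TRUE, extrapolated = extrap, fit = fit),
            class = "rf_estimate")
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat(sprintf(
    "RF estimate: center (%.4g, %.4g) deg, SDs (%.4g, %.4g) deg, size %.4g deg%s\n",
    x$center[1], x$center[2], x$sigmas[1], x$sigmas[2], x$size,
    if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Select center sites by RF-center distance
#'
#' Sites whose fitted RF center lies within `radius` degrees (Euclidean,
#' boundary inclusive) of the stimulus center.
#'
#' @param rf_centers data.frame with columns `azimuth` and `elevation`
#'   (one row per site).
#' @param stimulus_center Numeric `c(azimuth, elevation)`.
#' @param radius Selection radius in degrees (positive); the study
#'   convention is 0.2 or 0.15 degrees depending on the dataset.
#' @return Integer vector of selected row indices.
#' @export
select_center_sites <- function(rf_centers, stimulus_center, radius) {
  stopifnot(is.data.frame(rf_centers),
            all(c("azimuth", "elevation") %in% names(rf_centers)),
            length(stimulus_center) == 2L, radius > 0)
  d <- sqrt((rf_centers$azimuth - stimulus_center[1])^2 +
            (rf_centers$elevation - stimulus_center[2])^2)
  which(d <= radius)
}
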