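#' Input-plane map of steady responses and oscillation metrics
#'
#' Simulates the network over a grid of external drives (iE, iI) and
#' records, per cell, the post-transient mean E and I responses and the
#' oscillation metrics (peak power, frequency, amplitude, sustained
#' flag), together with the local-curvature regime flags at the cell's
#' fixed point.  Cells whose simulation or classification fails are
#' recorded as missing rather than aborting the sweep.
#'
#' @param spec An [ei_model_spec()].
#' @param iE_axis,iI_axis Ascending numeric grids of external drives.
#' @param duration_ms,dt_ms,transient_ms Simulation settings per cell.
#' @param search_band Passed to [oscillation_metrics()].
#' @return Object of class `input_plane_map`: the axes plus matrices
#'   (`length(iE_axis)` x `length(iI_axis)`) `E_map`, `I_map`,
#'   `power_map`, `freq_map`, `amp_map`, and logical `sustained`,
#'   `e_sublinear`, `i_superlinear`.
#' @examples
#' m <- input_plane_map(ei_model_spec(), c(3), c(6, 7.5),
#'                      duration_ms = 1500)
#' m$freq_map
#' @export
input_plane_map <- function(spec, iE_axis, iI_axis, duration_ms = 3000,
                            dt_ms = 0.05, transient_ms = 1000,
                            search_band = c(10, 150)) {
  stopifnot(inherits(spec, "ei_model_spec"),
            all(is.finite(iE_axis)), all(is.finite(iI_axis)),
            !is.unsorted(iE_axis, strictly = TRUE),
            !is.unsorted(iI_axis, strictly = TRUE))
  ne <- length(iE_axis); ni <- length(iI_axis)
  mk <- function() matrix(NA_real_, ne, ni, dimnames = list(iE_axis, iI_axis))
  E_map <- mk(); I_map <- mk(); power_map <- mk(); freq_map <- mk()
  amp_map <- mk()
  sustained <- matrix(NA, ne, ni); e_sub <- matrix(NA, ne, ni)
  i_sup <- matrix(NA, ne, ni)
  w <- effective_weights(spec)
  for (a in seq_len(ne)) for (b in seq_len(ni)) {
    cell <- tryCatch({
      tr <- simulate_ei(spec, iE_axis[a], iI_axis[b],
                        duration_ms = duration_ms, dt_ms = dt_ms)
      keep <- tr$times >= transient_ms
      om <- oscillation_metrics(tr, transient_ms = transient_ms,
                                search_band = search_band)
      fps <- find_fixed_points(spec, iE_axis[a], iI_axis[b])
      flags <- c(NA, NA)
      if (nrow(fps) == 1L) {
        dE <- w$wee * fps$E - w$wei * fps$I + iE_axis[a]
        dI <- w$wie * fps$E - w$wii * fps$I + iI_axis[b]
        flags <- c(sigmoid_curvature(dE, spec$e_params) < 0,
                   sigmoid_curvature(dI, spec$i_params) > 0)
      }
      list(mE = mean(tr$E[keep]), mI = mean(tr$I[keep]), om = om,
           flags = flags)
    }, error = function(e) NULL)
    if (is.null(cell)) next
    E_map[a, b] <- cell$mE; I_map[a, b] <- cell$mI
    power_map[a, b] <- cell$om$peak_power
    freq_map[a, b] <- cell$om$peak_frequency
    amp_map[a, b] <- cell$om$amplitude
    sustained[a, b] <- cell$om$sustained
    e_sub[a, b] <- cell$flags[1]; i_sup[a, b] <- cell$flags[2]
  }
  structure(list(iE_axis = iE_axis, iI_axis = iI_axis,
                 E_map = E_map, I_map = I_map, power_map = power_map,
                 freq_map = freq_map, amp_map = amp_map,
                 sustained = sustained, e_sublinear = e_sub,
                 i_superlinear = i_sup),
            class = "input_plane_map")
}

#' Weight-perturbation (discontinuity) experiment
#'
#' For each scale, reduces the named effective weight via
#' [apply_discontinuity()], simulates at the given drive, and reports the
#' oscillation metrics together with the relative shift of the fixed
#' point versus the unperturbed network (Euclidean norm of the fixed
#' point displacement divided by the norm of the unperturbed fixed
#' point).
#'
#' @param spec An [ei_model_spec()].
#' @param weight_name One of `"wee"`, `"wei"`, `"wie"`, `"wii"`.
#' @param scales Numeric vector of multipliers in `[0, 1]`.
#' @param iE,iI External drives.
#' @param duration_ms,dt_ms,transient_ms Simulation settings.
#' @return data.frame with one row per scale (in the given order):
#'   `scale`, `peak_power`, `peak_frequency`, `amplitude`, `sustained`,
#'   `E_star`, `I_star`, `fixed_point_shift`.
#' @examples
#' weight_perturbation_experiment(ei_model_spec(), "wee", c(1, 0.9, 0.8),
#'                                iE = 3, iI = 7.5, duration_ms = 2000)
#' @export
weight_perturbation_experiment <- function(spec, weight_name, scales,
                                           iE, iI, duration_ms = 4000,
                                           dt_ms = 0.05,
                                           transient_ms = 1000) {
  stopifnot(is.numeric(scales), all(scales >= 0 & scales <= 1))
  base_fp <- find_fixed_points(spec, iE, iI)
  if (nrow(base_fp) != 1L)
    stop("perturbation experiment needs a unique unperturbed fixed point")
  ref <- c(base_fp$E, base_fp$I)
  rows <- lapply(scales, function(sc) {
    sp <- apply_discontinuity(spec, weight_name, sc)
    tr <- simulate_ei(sp, iE, iI, duration_ms = duration_ms, dt_ms = dt_ms)
    om <- oscillation_metrics(tr, transient_ms = transient_ms)
    fp <- find_fixed_points(sp, iE, iI)
    shift <- if (nrow(fp) == 1L)
      sqrt(sum((c(fp$E, fp$I) - ref)^2)) / sqrt(sum(ref^2))
    else NA_real_
    data.frame(scale = sc, peak_power = om$peak_power,
               peak_frequency = om$peak_frequency,
               amplitude = om$amplitude, sustained = om$sustained,
               E_star = if (nrow(fp) == 1L) fp$E else NA_real_,
               I_star = if (nrow(fp) == 1L) fp$I else NA_real_,
               fixed_point_shift = shift)
  })
  do.call(rbind, rows)
}

#' Hopf bifurcation scan along the inhibitory drive
#'
#' Follows the fixed-point branch along an iI sweep at fixed iE (Newton
#' seeded from the previous point), locating the first sign change of the
#' leading eigenvalue's real part, then determines by simulation the
#' first drive at which the oscillation is sustained.  Long simulations
#' are restricted to a window around the eigenvalue crossing, since
#' convergence onto the limit cycle slows near the bifurcation.
#'
#' @param spec An [ei_model_spec()].
#' @param iE Fixed excitatory drive.
#' @param iI_range Range of inhibitory drives to scan.
#' @param step Sweep step (default 0.1).
#' @param sim_window Half-width (in iI units) of the window around the
#'   eigenvalue crossing inside which simulations are run (default 1).
#' @param duration_ms,dt_ms,transient_ms Simulation settings inside the
#'   window; the duration default is long (20 s) because settling onto a
#'   small near-Hopf limit cycle takes tens of seconds of model time.
#' @return List of class `hopf_scan`: `branch` (data.frame iI, E, I, re,
#'   im), `eigen_crossing` (interval c(lo, hi) bracketing the real-part
#'   zero), `first_sustained` (iI), `sim` (data.frame of simulated
#'   amplitudes), and `supercritical` (amplitude small at onset and
#'   growing continuously).
#' @export
hopf_scan <- function(spec, iE = 3, iI_range = c(0, 20), step = 0.1,
                      sim_window = 1, duration_ms = 20000, dt_ms = 0.05,
                      transient_ms = 2000) {
  iI_vals <- seq(iI_range[1], iI_range[2], by = step)
  w <- effective_weights(spec)
  # operating branch: follow the fixed point the driven network sits on,
  # anchored at the first sweep point by a short simulation
  tr0 <- simulate_ei(spec, iE, iI_vals[1], duration_ms = 2000,
                     dt_ms = dt_ms)
  anchor <- c(mean(tr0$E[tr0$times >= 1000]),
              mean(tr0$I[tr0$times >= 1000]))
  v <- NULL
  branch <- matrix(NA_real_, length(iI_vals), 4)
  for (k in seq_along(iI_vals)) {
    iI <- iI_vals[k]
    g <- function(v) {
      r <- ei_residual(spec, v[1], v[2], iE, iI)
      c(r$g1, r$g2)
    }
    vk <- NULL
    if (!is.null(v)) {
      # damped Newton continuation from the previous branch point
      vt <- v
      for (it in seq_len(200)) {
        dEs <- sigmoid_slope(w$wee * vt[1] - w$wei * vt[2] + iE,
                             spec$e_params)
        dIs <- sigmoid_slope(w$wie * vt[1] - w$wii * vt[2] + iI,
                             spec$i_params)
        J <- matrix(c(-1 + w$wee * dEs, w$wie * dIs,
                      -w$wei * dEs, -1 - w$wii * dIs), 2)
        st <- tryCatch(solve(J, -g(vt)), error = function(e) c(0, 0))
        lam <- 1; g0 <- sum(abs(g(vt)))
        repeat {
          vn <- vt + lam * st
          if (sum(abs(g(vn))) <= g0 || lam < 1e-8) break
          lam <- lam / 2
        }
        vt <- vn
        if (max(abs(lam * st)) < 1e-13) break
      }
      if (max(abs(g(vt))) < 1e-9) vk <- vt
    }
    if (is.null(vk)) {
      # continuation failed (or first point): global root set, nearest
      # to the previous branch point / simulation anchor
      fps <- find_fixed_points(spec, iE, iI)
      if (!nrow(fps)) stop("no fixed point found at iI = ", iI)
      ref <- if (is.null(v)) anchor else v
      j <- which.min((fps$E - ref[1])^2 + (fps$I - ref[2])^2)
      vk <- c(fps$E[j], fps$I[j])
    }
    v <- vk
    ev <- eigen(ei_jacobian(spec, v[1], v[2], iE, iI),
                only.values = TRUE)$values
    j <- which.max(Re(ev))
    branch[k, ] <- c(v, Re(ev[j]), abs(Im(ev[j])))
  }
  branch <- data.frame(iI = iI_vals, E = branch[, 1], I = branch[, 2],
                       re = branch[, 3], im = branch[, 4])
  sgn <- sign(branch$re)
  cross_idx <- which(diff(sgn) > 0)   # stable -> unstable
  if (!length(cross_idx))
    stop("no destabilizing eigenvalue crossing found in the scanned range")
  c1 <- cross_idx[1]
  eigen_crossing <- c(iI_vals[c1], iI_vals[c1 + 1])

  # empirical sustained-oscillation onset near the crossing
  in_win <- iI_vals >= eigen_crossing[1] - sim_window &
            iI_vals <= eigen_crossing[2] + sim_window
  sim_iI <- iI_vals[in_win]
  sim <- data.frame(iI = sim_iI, amplitude = NA_real_, sustained = NA)
  for (k in seq_along(sim_iI)) {
    om <- oscillation_metrics(
      simulate_ei(spec, iE, sim_iI[k], duration_ms = duration_ms,
                  dt_ms = dt_ms),
      transient_ms = transient_ms)
    sim$amplitude[k] <- om$amplitude
    sim$sustained[k] <- om$sustained
  }
  fs <- which(sim$sustained)
  first_sustained <- if (length(fs)) sim$iI[fs[1]] else NA_real_

  # supercritical: amplitude grows continuously from ~0 past onset
  supercritical <- NA
  if (length(fs) >= 5) {
    a <- sim$amplitude[fs[1:5]]
    supercritical <- all(diff(a) > 0) && a[1] < 0.5 * a[5]
  }
  structure(list(branch = branch, eigen_crossing = eigen_crossing,
                 first_sustained = first_sustained, sim = sim,
                 supercritical = supercritical, iE = iE),
            class = "hopf_scan")
}

#' @export
print.hopf_scan <- function(x, ...) {
  cat(sprintf(
    "Hopf scan at iE = %g: eigenvalue crossing in (%g, %g], first sustained oscillation at iI = %g\n",
    x$iE, x$eigen_crossing[1], x$eigen_crossing[2], x$first_sustained))
  cat(sprintf("  supercritical (continuous amplitude growth): %s\n",
              x$supercritical))
  invisible(x)
}
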