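#' Oscillation metrics of a simulated trajectory
#'
#' After discarding the transient, the oscillation frequency is estimated
#' from the mean interval between upward zero crossings of the
#' mean-subtracted E series (sub-sample precision by linear
#' interpolation), and cross-checked against the periodogram maximum.
#' Amplitude is the median peak-to-trough excursion per cycle.  The
#' oscillation is labelled *sustained* when the amplitude exceeds a
#' configurable floor and changes by less than 5% between the last two
#' 500 ms half-windows.
#'
#' @param traj An `ei_trajectory` from [simulate_ei()], or a list with
#'   numeric `E` and `dt_ms` (a trajectory at least `transient_ms` +
#'   1000 ms long).
#' @param transient_ms Initial transient to discard (default 500 ms).
#' @param search_band Frequency range (Hz) searched for the periodogram
#'   peak (default 10-150 Hz).
#' @param amp_floor Sustained-amplitude floor (activity units, default
#'   1e-3).
#' @return List of class `oscillation_metrics`: `peak_frequency` (Hz,
#'   zero-crossing estimate; 0 when no crossings), `periodogram_frequency`
#'   (Hz), `peak_power` (periodogram maximum in `search_band`),
#'   `amplitude`, `sustained`, `n_cycles`.
#' @examples
#' tr <- simulate_ei(ei_model_spec(), 3, 7.5, duration_ms = 2000)
#' oscillation_metrics(tr)
#' @export
oscillation_metrics <- function(traj, transient_ms = 500,
                                search_band = c(10, 150), amp_floor = 1e-3) {
  stopifnot(is.numeric(traj$E), is.numeric(traj$dt_ms))
  dt <- traj$dt_ms
  times <- if (!is.null(traj$times)) traj$times else seq_along(traj$E) * dt - dt
  total <- max(times)
  if (total < transient_ms + 1000)
    stop("trajectory must extend at least 1000 ms beyond the transient")
  keep <- times >= transient_ms
  E <- traj$E[keep]
  Ec <- E - mean(E)

  # upward zero crossings with linear interpolation
  s <- Ec[-length(Ec)]; s2 <- Ec[-1]
  idx <- which(s < 0 & s2 >= 0)
  cross <- idx + s[idx] / (s[idx] - s2[idx])   # fractional sample index
  freq <- if (length(cross) >= 2) 1000 / (mean(diff(cross)) * dt) else 0

  # per-cycle peak-to-trough amplitude
  amps <- numeric(0)
  if (length(idx) >= 2) {
    for (k in seq_len(length(idx) - 1)) {
      seg <- Ec[idx[k]:idx[k + 1]]
      amps <- c(amps, max(seg) - min(seg))
    }
  }
  amplitude <- if (length(amps)) stats::median(amps) else 0

  # periodogram of the post-transient E series; Hann window plus 4x
  # zero-padding suppress scalloping so peak power varies smoothly
  n <- length(Ec)
  fs <- 1000 / dt
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  npad <- 2^ceiling(log2(4 * n))
  pw <- Mod(stats::fft(c(Ec * hann, numeric(npad - n))))^2 / n
  nf <- floor(npad / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / npad
  pw <- pw[seq_len(nf)]
  inband <- freqs >= search_band[1] & freqs <= search_band[2]
  if (any(inband)) {
    peak_power <- max(pw[inband])
    pfreq <- freqs[inband][which.max(pw[inband])]
  } else {
    peak_power <- 0; pfreq <- 0
  }

  # sustained: amplitude floor + <5% change across the last two 500 ms windows
  sustained <- FALSE
  if (amplitude > amp_floor && length(idx) >= 2) {
    t_rel <- times[keep] - transient_ms
    tmax <- max(t_rel)
    w2 <- Ec[t_rel >= tmax - 500]
    w1 <- Ec[t_rel >= tmax - 1000 & t_rel < tmax - 500]
    if (length(w1) && length(w2)) {
      a1 <- max(w1) - min(w1); a2 <- max(w2) - min(w2)
      sustained <- abs(a2 - a1) / max(a1, a2, 1e-12) < 0.05 && a2 > amp_floor
    }
  }

  structure(list(peak_frequency = freq, periodogram_frequency = pfreq,
                 peak_power = peak_power, amplitude = amplitude,
                 sustained = sustained, n_cycles = length(amps),
                 freq_resolution = fs / n),
            class = "oscillation_metrics")
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf(
    "oscillation: %.2f Hz (periodogram %.2f Hz), amplitude %.4g, %s\n",
    x$peak_frequency, x$periodogram_frequency, x$amplitude,
    if (x$sustained) "sustained" else "not sustained"))
  invisible(x)
}
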