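#' 1/f-type noise trials by spectral shaping
#'
#' White Gaussian noise filtered in the frequency domain with gain
#' `f^(-beta/2)` (DC removed), giving a power spectrum proportional to
#' `1/f^beta`.
#'
#' @param n_samples Samples per trial.
#' @param n_trials Number of trials.
#' @param fs Sampling rate (Hz).
#' @param beta Spectral exponent (default 1).
#' @param scale Output standard-deviation scale (arbitrary units).
#' @return `n_trials x n_samples` matrix.  Uses the current RNG stream.
#' @export
one_over_f_noise <- function(n_samples, n_trials, fs, beta = 1,
                             scale = 1) {
  stopifnot(n_samples > 8, n_trials >= 1, fs > 0, beta >= 0)
  n <- n_samples
  freqs <- c(0, seq_len(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)       # two-sided axis
  gain <- c(0, freqs[-1]^(-beta / 2))
  out <- matrix(0, n_trials, n)
  for (tr in seq_len(n_trials)) {
    x <- stats::rnorm(n)
    y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
    out[tr, ] <- y / stats::sd(y) * scale
  }
  out
}

#' Synthetic-session configuration
#'
#' Defines the structure and ground-truth laws of a generated session:
#' trials sampled at `fs` over `t_range` seconds around stimulus onset
#' (stimulus on during `stim_window`); a stimulus-evoked narrowband gamma
#' component whose amplitude decays exponentially with discontinuity
#' magnitude `d` as `A0 * exp(-d / lambda)` and whose frequency rises as
#' `f0 + k * d`; 1/f-type baseline noise; and inhomogeneous-Poisson
#' spiking whose stimulus rate follows `r0 * (1 + s * d)` with per-unit
#' lognormal heterogeneity.
#'
#' @param discontinuity_levels Magnitudes in degrees (default the annulus
#'   widths `c(0, 0.025, 0.05, 0.1, 0.2)`).
#' @param n_trials Trials per condition (default 20; at least 2).
#' @param fs Sampling rate (Hz, default 2000).
#' @param t_range Trial span in seconds around onset (default
#'   `c(-1, 1)`).
#' @param stim_window Stimulus-on epoch in seconds (default
#'   `c(0, 0.8)`).
#' @param gamma_amp Base gamma amplitude `A0`; the default gives an
#'   in-band signal-to-noise ratio of about 10 dB over the default
#'   noise.
#' @param gamma_freq Base gamma frequency `f0` in Hz (default 50, inside
#'   the 35-65 Hz analysis band).
#' @param attenuation_lambda Amplitude decay constant `lambda` in degrees
#'   (default 0.1; must be positive, may be `Inf` for no attenuation).
#' @param freq_slope Frequency rise `k` in Hz/degree (default 20).
#' @param noise_beta,noise_scale 1/f noise exponent and scale.
#' @param ramp_ms Onset/offset raised-cosine ramp of the gamma component
#'   (default 50 ms).
#' @param rate_base Baseline firing rate per unit (spikes/s, default 5).
#' @param rate_stim Stimulus firing rate `r0` at zero discontinuity
#'   (default 20).
#' @param rate_slope Rate slope `s` per degree (default 1).
#' @param n_units Units per session (default 8).
#' @param unit_sdlog SD (log scale) of the per-unit lognormal
#'   heterogeneity factor (default 0.3).
#' @param seed Integer seed; identical configuration and seed give
#'   identical sessions.
#' @return List of class `session_config`.
#' @export
session_config <- function(discontinuity_levels = c(0, 0.025, 0.05, 0.1, 0.2),
                           n_trials = 20, fs = 2000, t_range = c(-1, 1),
                           stim_window = c(0, 0.8),
                           gamma_amp = 1.25, gamma_freq = 50,
                           attenuation_lambda = 0.1, freq_slope = 20,
                           noise_beta = 1, noise_scale = 1, ramp_ms = 50,
                           rate_base = 5, rate_stim = 20, rate_slope = 1,
                           n_units = 8, unit_sdlog = 0.3, seed = 1) {
  cfg <- list(discontinuity_levels = discontinuity_levels,
              n_trials = n_trials, fs = fs, t_range = t_range,
              stim_window = stim_window, gamma_amp = gamma_amp,
              gamma_freq = gamma_freq,
              attenuation_lambda = attenuation_lambda,
              freq_slope = freq_slope, noise_beta = noise_beta,
              noise_scale = noise_scale, ramp_ms = ramp_ms,
              rate_base = rate_base, rate_stim = rate_stim,
              rate_slope = rate_slope, n_units = n_units,
              unit_sdlog = unit_sdlog, seed = seed)
  if (cfg$n_trials < 2) stop("n_trials must be at least 2")
  if (cfg$attenuation_lambda <= 0) stop("attenuation_lambda must be > 0")
  if (cfg$fs <= 0 || cfg$gamma_freq <= 0 || cfg$gamma_amp < 0)
    stop("invalid config field")
  if (diff(cfg$t_range) <= 0 || cfg$t_range[1] > -0.5)
    stop("trial span must start at least 0.5 s before onset")
  if (cfg$t_range[2] < cfg$stim_window[2])
    stop("trial span must cover the stimulus epoch")
  structure(cfg, class = "session_config")
}

# raised-cosine on/off ramp applied to the stimulus-epoch envelope
.stim_envelope <- function(t, stim_window, ramp_ms) {
  env <- as.numeric(t >= stim_window[1] & t < stim_window[2])
  r <- ramp_ms / 1000
  if (r > 0) {
    on <- t >= stim_window[1] & t < stim_window[1] + r
    off <- t >= stim_window[2] - r & t < stim_window[2]
    env[on] <- 0.5 * (1 - cos(pi * (t[on] - stim_window[1]) / r))
    env[off] <- 0.5 * (1 - cos(pi * (stim_window[2] - t[off]) / r))
  }
  env
}

.poisson_spikes <- function(rate, t_lo, t_hi) {
  if (rate <= 0 || t_hi <= t_lo) return(numeric(0))
  k <- stats::rpois(1, rate * (t_hi - t_lo))
  sort(stats::runif(k, t_lo, t_hi))
}

#' Generate a noise-driven synthetic session
#'
#' Per condition `d`: LFP trials are 1/f-type noise plus, during the
#' stimulus epoch only, a sinusoid of amplitude `A0 * exp(-d/lambda)` and
#' frequency `f0 + k*d` with a random phase per trial and raised-cosine
#' onset/offset ramps.  Spikes are inhomogeneous Poisson: baseline rate
#' outside the stimulus epoch and `r0 * (1 + s*d)` inside, both scaled by
#' a per-unit lognormal heterogeneity factor.  Identical config and seed
#' give identical output.
#'
#' @param cfg A [session_config()].
#' @return Object of class `ei_session`: `trials` (list of
#'   [trial_set()] per condition), `spikes` (a [spike_set()]),
#'   `conditions` (data.frame `label`, `magnitude`), `truth`
#'   (programmed per-condition amplitude, frequency and per-unit rates,
#'   plus the generating laws), and `config`.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(diff(cfg$t_range) * fs)
  t <- cfg$t_range[1] + (seq_len(n) - 1) / fs
  t0_index <- which.min(abs(t))
  env <- .stim_envelope(t, cfg$stim_window, cfg$ramp_ms)
  d_levels <- cfg$discontinuity_levels
  ncond <- length(d_levels)

  amp <- cfg$gamma_amp * exp(-d_levels / cfg$attenuation_lambda)
  freq <- cfg$gamma_freq + cfg$freq_slope * d_levels
  het <- stats::rlnorm(cfg$n_units, 0, cfg$unit_sdlog)

  trials <- vector("list", ncond)
  for (cc in seq_len(ncond)) {
    lfp <- one_over_f_noise(n, cfg$n_trials, fs, cfg$noise_beta,
                            cfg$noise_scale)
    for (tr in seq_len(cfg$n_trials)) {
      phi <- stats::runif(1, 0, 2 * pi)
      lfp[tr, ] <- lfp[tr, ] +
        amp[cc] * env * sin(2 * pi * freq[cc] * t + phi)
    }
    trials[[cc]] <- trial_set(lfp, fs, t0_index,
                              condition = list(label = paste0("d", cc),
                                               magnitude = d_levels[cc]))
  }

  rate_stim <- cfg$rate_stim * (1 + cfg$rate_slope * d_levels)
  units <- vector("list", cfg$n_units)
  names(units) <- paste0("unit", seq_len(cfg$n_units))
  for (u in seq_len(cfg$n_units)) {
    per_cond <- vector("list", ncond)
    for (cc in seq_len(ncond)) {
      per_cond[[cc]] <- lapply(seq_len(cfg$n_trials), function(tr) {
        sort(c(.poisson_spikes(cfg$rate_base * het[u], cfg$t_range[1],
                               cfg$stim_window[1]),
               .poisson_spikes(rate_stim[cc] * het[u],
                               cfg$stim_window[1], cfg$stim_window[2]),
               .poisson_spikes(cfg$rate_base * het[u],
                               cfg$stim_window[2], cfg$t_range[2])))
      })
    }
    units[[u]] <- per_cond
  }
  conditions <- data.frame(label = paste0("d", seq_len(ncond)),
                           magnitude = d_levels)
  truth <- list(amplitude = amp, frequency = freq,
                rates = outer(het, rate_stim),
                heterogeneity = het,
                attenuation_lambda = cfg$attenuation_lambda,
                freq_slope = cfg$freq_slope, rate_slope = cfg$rate_slope)
  structure(list(trials = trials,
                 spikes = spike_set(units, conditions, cfg$t_range),
                 conditions = conditions, truth = truth, config = cfg,
                 t = t, fs = fs, t0_index = t0_index),
            class = "ei_session")
}

#' Generate a model-driven synthetic session
#'
#' Realizes the discontinuity as effective-weight scaling: for each
#' condition the E-I network is simulated with the mapped weight scale,
#' and the post-transient, mean-subtracted E activity (resampled to the
#' session sampling rate and scaled) is used as the stimulus-epoch
#' additive component over 1/f noise.  Trials differ by their noise
#' realization and by a random circular offset into the model trace.
#'
#' @param spec An [ei_model_spec()].
#' @param scales Weight scales per condition (monotone non-increasing in
#'   the discontinuity magnitude), same length as the configured levels.
#' @param cfg A [session_config()]; the gamma fields are ignored in this
#'   mode (the model supplies the oscillation).
#' @param weight_name Effective weight to scale (default `"wee"`).
#' @param iE,iI External drives (default the oscillatory operating point
#'   3 and 7.5).
#' @param component_scale Amplitude multiplier applied to the
#'   (unit-variance-free) model E trace before injection (default 60,
#'   which puts the default-network oscillation well above the noise
#'   floor so that weakened conditions remain measurable).
#' @param transient_ms Model transient discarded before resampling
#'   (default 3000 ms: long enough that damped conditions have fully
#'   settled, so their injected component reflects the asymptotic state
#'   rather than leftover ring-down).
#' @return An `ei_session` (as [generate_session()]); `truth` carries the
#'   per-condition model oscillation metrics and applied scales.
#' @export
generate_model_driven_session <- function(spec, scales, cfg,
                                          weight_name = "wee",
                                          iE = 3, iI = 7.5,
                                          component_scale = 60,
                                          transient_ms = 3000) {
  stopifnot(inherits(spec, "ei_model_spec"),
            inherits(cfg, "session_config"),
            length(scales) == length(cfg$discontinuity_levels))
  if (is.unsorted(rev(scales)))
    stop("scales must be monotone non-increasing in the discontinuity level")
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(diff(cfg$t_range) * fs)
  t <- cfg$t_range[1] + (seq_len(n) - 1) / fs
  t0_index <- which.min(abs(t))
  env <- .stim_envelope(t, cfg$stim_window, cfg$ramp_ms)
  stim_idx <- which(env > 0)
  ncond <- length(scales)

  dt_ms <- 0.05
  keep_every <- round(1000 / fs / dt_ms)   # model steps per LFP sample
  seg_ms <- 2500
  comps <- vector("list", ncond)
  met <- vector("list", ncond)
  for (cc in seq_len(ncond)) {
    sp <- apply_discontinuity(spec, weight_name, scales[cc])
    trj <- simulate_ei(sp, iE, iI, duration_ms = transient_ms + seg_ms,
                       dt_ms = dt_ms)
    met[[cc]] <- oscillation_metrics(trj, transient_ms = transient_ms)
    keep <- trj$times >= transient_ms
    e <- trj$E[keep][seq(1, sum(keep), by = keep_every)]
    comps[[cc]] <- (e - mean(e)) * component_scale
  }

  trials <- vector("list", ncond)
  for (cc in seq_len(ncond)) {
    lfp <- one_over_f_noise(n, cfg$n_trials, fs, cfg$noise_beta,
                            cfg$noise_scale)
    comp <- comps[[cc]]
    for (tr in seq_len(cfg$n_trials)) {
      off <- sample.int(length(comp), 1)
      idx <- ((off + seq_along(stim_idx) - 2) %% length(comp)) + 1
      lfp[tr, stim_idx] <- lfp[tr, stim_idx] +
        comp[idx] * env[stim_idx]
    }
    trials[[cc]] <- trial_set(lfp, fs, t0_index,
                              condition = list(label = paste0("d", cc),
                                               magnitude =
                                                 cfg$discontinuity_levels[cc]))
  }
  conditions <- data.frame(label = paste0("d", seq_len(ncond)),
                           magnitude = cfg$discontinuity_levels)
  truth <- list(scales = scales, weight_name = weight_name,
                metrics = met, component_scale = component_scale,
                iE = iE, iI = iI)
  # spiking reuses the noise-driven rate law
  rate_stim <- cfg$rate_stim * (1 + cfg$rate_slope *
                                  cfg$discontinuity_levels)
  het <- stats::rlnorm(cfg$n_units, 0, cfg$unit_sdlog)
  units <- vector("list", cfg$n_units)
  names(units) <- paste0("unit", seq_len(cfg$n_units))
  for (u in seq_len(cfg$n_units)) {
    per_cond <- vector("list", ncond)
    for (cc in seq_len(ncond)) {
      per_cond[[cc]] <- lapply(seq_len(cfg$n_trials), function(tr) {
        sort(c(.poisson_spikes(cfg$rate_base * het[u], cfg$t_range[1],
                               cfg$stim_window[1]),
               .poisson_spikes(rate_stim[cc] * het[u],
                               cfg$stim_window[1], cfg$stim_window[2]),
               .poisson_spikes(cfg$rate_base * het[u],
                               cfg$stim_window[2], cfg$t_range[2])))
      })
    }
    units[[u]] <- per_cond
  }
  structure(list(trials = trials,
                 spikes = spike_set(units, conditions, cfg$t_range),
                 conditions = conditions, truth = truth, config = cfg,
                 t = t, fs = fs, t0_index = t0_index,
                 model_driven = TRUE),
            class = "ei_session")
}

#' Generate a synthetic receptive-field mapping grid
#'
#' Responses on a rectangular grid are samples of a known axis-aligned 2D
#' Gaussian plus i.i.d. Gaussian noise; seeded and deterministic.
#'
#' @param center True RF center `c(azimuth, elevation)` in degrees.
#' @param sigmas True SDs `c(sd_az, sd_el)` in degrees.
#' @param amplitude Peak response amplitude (default 1).
#' @param noise_sd Response noise SD (0 gives exact Gaussian samples).
#' @param grid_span Half-width of the square grid in degrees (default
#'   1); the grid must cover the true center.
#' @param n_side Grid points per side (default 9).
#' @param grid_center Center of the grid (defaults to `center` rounded to
#'   the grid pitch).
#' @param seed Integer seed.
#' @return List with `grid` (data.frame `azimuth`, `elevation`,
#'   `response`) and `truth`.
#' @export
generate_rf_grid <- function(center, sigmas, amplitude = 1, noise_sd = 0,
                             grid_span = 0.4, n_side = 9,
                             grid_center = c(0, 0), seed = 1) {
  stopifnot(length(center) == 2L, length(sigmas) == 2L, all(sigmas > 0),
            noise_sd >= 0, n_side >= 3)
  az <- seq(grid_center[1] - grid_span, grid_center[1] + grid_span,
            length.out = n_side)
  el <- seq(grid_center[2] - grid_span, grid_center[2] + grid_span,
            length.out = n_side)
  if (center[1] < min(az) || center[1] > max(az) ||
      center[2] < min(el) || center[2] > max(el))
    stop("grid does not cover the true RF center")
  g <- expand.grid(azimuth = az, elevation = el)
  mu <- amplitude * exp(-((g$azimuth - center[1])^2 / (2 * sigmas[1]^2) +
                          (g$elevation - center[2])^2 / (2 * sigmas[2]^2)))
  set.seed(seed)
  g$response <- mu + stats::rnorm(nrow(g), 0, noise_sd)
  list(grid = g,
       truth = list(center = center, sigmas = sigmas,
                    amplitude = amplitude, noise_sd = noise_sd))
}
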