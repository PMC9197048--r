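# cache for computed tapers (keyed by n and nw)
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) taper
#'
#' First-order DPSS taper of length `n` with time-bandwidth product `nw`,
#' computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences.  Normalized to unit energy and
#' positive mean.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 1, matching a 0.25 s window
#'   with 4 Hz resolution).
#' @return Numeric vector of length `n` with `sum(taper^2) == 1`.
#' @export
dpss_taper <- function(n, nw = 1) {
  stopifnot(n >= 8, nw > 0)
  key <- paste0(n, "_", nw)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  W <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  .taper_cache[[key]] <- v
  v
}

#' Single-taper power spectral density of one segment
#'
#' Mean-removes the segment, applies the taper, and returns the one-sided
#' periodogram.  Units are arbitrary (only ratios, i.e. decibel, matter
#' downstream); interior bins carry the doubled two-sided power.
#'
#' @param x Numeric segment.
#' @param fs Sampling rate (Hz).
#' @param taper Taper vector of `length(x)` (default the unit-energy DPSS
#'   taper from [dpss_taper()]); use `"cosine"` for the split-cosine
#'   tapered-periodogram fallback.
#' @return List with `freqs` (Hz) and `power`.
#' @export
taper_psd <- function(x, fs, taper = NULL) {
  n <- length(x)
  if (is.null(taper)) taper <- dpss_taper(n)
  else if (identical(taper, "cosine")) {
    taper <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
    taper <- taper / sqrt(sum(taper^2))
  }
  stopifnot(length(taper) == n)
  x <- x - mean(x)
  y <- stats::fft(taper * x)
  nf <- floor(n / 2) + 1
  p <- Mod(y[seq_len(nf)])^2
  # double interior bins (one-sided convention)
  last <- if (n %% 2 == 0) nf - 1 else nf
  if (last >= 2) p[2:last] <- 2 * p[2:last]
  list(freqs = (seq_len(nf) - 1) * fs / n, power = p)
}

#' Trial container for LFP analysis
#'
#' Trials x samples matrix of LFP with its sampling rate, the sample
#' index of stimulus onset, and a condition label.  Sample `j` is at time
#' `(j - t0_index) / fs` seconds relative to onset.  Requires at least
#' 0.5 s of pre-onset and 0.8 s of post-onset span.
#'
#' @param lfp Numeric matrix, trials in rows.
#' @param fs Sampling rate in Hz (default 2000).
#' @param t0_index 1-based sample index of stimulus onset.
#' @param condition Optional list/label describing the condition (e.g.
#'   discontinuity type and magnitude).
#' @return Object of class `trial_set`.
#' @export
trial_set <- function(lfp, fs = 2000, t0_index, condition = NULL) {
  stopifnot(is.matrix(lfp), is.numeric(lfp), fs > 0,
            t0_index >= 1, t0_index <= ncol(lfp))
  pre_s <- (t0_index - 1) / fs
  post_s <- (ncol(lfp) - t0_index + 1) / fs
  if (pre_s < 0.5) stop("pre-onset span must be at least 0.5 s (got ",
                        round(pre_s, 3), " s)")
  if (post_s < 0.8) stop("post-onset span must be at least 0.8 s (got ",
                         round(post_s, 3), " s)")
  structure(list(lfp = lfp, fs = fs, t0_index = t0_index,
                 condition = condition,
                 times = (seq_len(ncol(lfp)) - t0_index) / fs),
            class = "trial_set")
}

# sample-index window [from, to) for times in seconds relative to onset
.window_idx <- function(ts, t_lo, t_hi) {
  i <- which(ts$times >= t_lo & ts$times < t_hi)
  if (!length(i)) stop("window outside the trial span")
  i
}

#' Time-frequency difference spectrum (dB from baseline)
#'
#' Sliding single-taper spectrogram: per window and trial a single-taper
#' power spectrum; powers are averaged across trials, log10-transformed,
#' and, per frequency, the mean log-spectrum over the baseline windows
#' (centers in -0.5 to 0 s) is subtracted; multiplying by 10 gives the
#' difference spectrum in decibel.
#'
#' @param ts A [trial_set()].
#' @param window_s Window length in seconds (default 0.25, i.e. 4 Hz
#'   resolution at 2 kHz).
#' @param step_s Window step (default 0.025 s).
#' @param taper Passed to [taper_psd()].
#' @return List of class `tf_spectrum`: `time_centers` (s, relative to
#'   onset), `freqs` (Hz), `values` (time x frequency, dB).
#' @export
tf_difference_spectrum <- function(ts, window_s = 0.25, step_s = 0.025,
                                   taper = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  ntr <- nrow(ts$lfp)
  if (ntr < 2) stop("need at least 2 trials")
  wlen <- round(window_s * ts$fs)
  step <- round(step_s * ts$fs)
  nsamp <- ncol(ts$lfp)
  starts <- seq(1, nsamp - wlen + 1, by = step)
  centers <- (starts + (wlen - 1) / 2 - ts$t0_index) / ts$fs
  nf <- floor(wlen / 2) + 1
  logmean <- matrix(NA_real_, length(starts), nf)
  freqs <- NULL
  for (k in seq_along(starts)) {
    sl <- starts[k]:(starts[k] + wlen - 1)
    acc <- 0
    for (tr in seq_len(ntr)) {
      p <- taper_psd(ts$lfp[tr, sl], ts$fs, taper)
      acc <- acc + p$power
      if (is.null(freqs)) freqs <- p$freqs
    }
    logmean[k, ] <- log10(acc / ntr)
  }
  base <- centers >= -0.5 & centers < 0
  if (!any(base)) stop("no baseline windows with centers in [-0.5, 0) s")
  base_log <- colMeans(logmean[base, , drop = FALSE])
  vals <- 10 * sweep(logmean, 2, base_log)
  structure(list(time_centers = centers, freqs = freqs, values = vals,
                 window_s = window_s, step_s = step_s),
            class = "tf_spectrum")
}

#' Stimulus-versus-baseline change in power
#'
#' Single-taper PSDs over the stimulus window (default 0.25-0.75 s after
#' onset) and the spontaneous baseline (default -0.5-0 s); trial-mean
#' power per frequency; `delta_db` is ten times the difference of the
#' log10 mean powers.
#'
#' @param ts A [trial_set()].
#' @param stim_window,base_window Analysis windows in seconds relative to
#'   onset.
#' @param taper Passed to [taper_psd()].
#' @return List of class `psd_change`: `freqs`, `delta_db`, `stim_power`,
#'   `base_power`, and the windows.
#' @export
change_in_power <- function(ts, stim_window = c(0.25, 0.75),
                            base_window = c(-0.5, 0), taper = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (nrow(ts$lfp) < 2) stop("need at least 2 trials")
  si <- .window_idx(ts, stim_window[1], stim_window[2])
  bi <- .window_idx(ts, base_window[1], base_window[2])
  if (length(si) != length(bi)) {
    n <- min(length(si), length(bi))
    si <- si[seq_len(n)]; bi <- bi[seq_len(n)]
  }
  stim_acc <- 0; base_acc <- 0; freqs <- NULL
  for (tr in seq_len(nrow(ts$lfp))) {
    ps <- taper_psd(ts$lfp[tr, si], ts$fs, taper)
    pb <- taper_psd(ts$lfp[tr, bi], ts$fs, taper)
    stim_acc <- stim_acc + ps$power
    base_acc <- base_acc + pb$power
    if (is.null(freqs)) freqs <- ps$freqs
  }
  ntr <- nrow(ts$lfp)
  stim_power <- stim_acc / ntr; base_power <- base_acc / ntr
  structure(list(freqs = freqs,
                 delta_db = 10 * (log10(stim_power) - log10(base_power)),
                 stim_power = stim_power, base_power = base_power,
                 stim_window = stim_window, base_window = base_window),
            class = "psd_change")
}

#' Gamma-band selection under the contrast rule
#'
#' Returns the configured band unchanged when at least one of the inner
#' or outer grating is at 100% contrast; when both are below 100%, both
#' band edges are shifted 5 Hz lower (gamma frequency decreases at low
#' contrast).
#'
#' @param config_band Numeric `c(lo, hi)` in Hz (e.g. `c(35, 65)` or
#'   `c(45, 75)`).
#' @param inner_contrast,outer_contrast Contrasts in percent, in
#'   `[0, 100]`.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' select_gamma_band(c(35, 65), 100, 50)  # unchanged
#' select_gamma_band(c(35, 65), 50, 50)   # c(30, 60)
#' @export
select_gamma_band <- function(config_band, inner_contrast, outer_contrast) {
  stopifnot(length(config_band) == 2L, config_band[1] > 0,
            config_band[1] < config_band[2])
  for (ct in c(inner_contrast, outer_contrast))
    if (!is.numeric(ct) || length(ct) != 1L || !is.finite(ct) ||
        ct < 0 || ct > 100)
      stop("contrasts must be single numbers in [0, 100]")
  if (inner_contrast == 100 || outer_contrast == 100) config_band
  else config_band - 5
}

#' Band power: sum of PSD over a frequency band
#'
#' Sum of spectral values at all frequency bins with
#' `lo <= f <= hi` (edges inclusive).
#'
#' @param freqs Frequency axis (Hz).
#' @param power Spectral values on that axis.
#' @param band Numeric `c(lo, hi)` in Hz.
#' @return Scalar band power.
#' @export
band_power <- function(freqs, power, band) {
  stopifnot(length(freqs) == length(power), length(band) == 2L)
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band [",
                      band[1], ", ", band[2], "] Hz")
  sum(power[sel])
}

#' Per-site normalization of band powers across conditions
#'
#' Divides each condition's band power by the maximum across conditions
#' for that site, so the maximum maps to exactly 1.  Idempotent.
#'
#' @param powers Named (or plain) numeric vector of per-condition powers;
#'   at least one value must be positive.
#' @return Vector of the same shape with maximum exactly 1.
#' @examples
#' normalized_band_power(c(a = 4, b = 2, c = 1))
#' @export
normalized_band_power <- function(powers) {
  stopifnot(is.numeric(powers), length(powers) >= 1)
  m <- max(powers)
  if (!is.finite(m) || m <= 0)
    stop("normalization requires at least one positive power")
  powers / m
}
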