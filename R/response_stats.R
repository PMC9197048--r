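#' Per-unit, per-trial spike-time container
#'
#' Ragged container of spike times (seconds, relative to stimulus onset):
#' a list of units, each a list over conditions, each a list of per-trial
#' numeric vectors.  Spike times must be sorted ascending and lie within
#' the trial bounds.
#'
#' @param units Named list as described above.
#' @param conditions data.frame describing the conditions (one row per
#'   condition; typically columns `label` and `magnitude`), with
#'   `nrow(conditions)` matching the per-unit condition count.
#' @param t_range Trial bounds `c(t_min, t_max)` in seconds.
#' @return Object of class `spike_set`.
#' @export
spike_set <- function(units, conditions, t_range = c(-1, 1)) {
  stopifnot(is.list(units), length(units) >= 1, is.data.frame(conditions))
  if (is.null(names(units)))
    names(units) <- paste0("unit", seq_along(units))
  ncond <- nrow(conditions)
  for (u in names(units)) {
    if (length(units[[u]]) != ncond)
      stop("unit '", u, "' does not have one entry per condition")
    for (cc in seq_len(ncond)) for (st in units[[u]][[cc]]) {
      if (length(st) && (is.unsorted(st) || min(st) < t_range[1] ||
                         max(st) > t_range[2]))
        stop("spike times of unit '", u, "' must be sorted and within ",
             "[", t_range[1], ", ", t_range[2], "] s")
    }
  }
  structure(list(units = units, conditions = conditions,
                 t_range = t_range), class = "spike_set")
}

unit_condition_rate <- function(trials, window) {
  if (!length(trials)) return(0)
  counts <- vapply(trials, function(st)
    sum(st >= window[1] & st <= window[2]), numeric(1))
  mean(counts) / diff(window)
}

#' Select spiking units by stimulus-period firing rate
#'
#' Keeps units whose mean firing rate in the stimulus window reaches
#' `min_rate` in at least one condition (boundary inclusive).
#'
#' @param spikes A [spike_set()].
#' @param stim_window Analysis window in seconds (default
#'   `c(0.25, 0.75)`).
#' @param min_rate Minimum mean rate in spikes/s (default 1).
#' @return Character vector of unit names.
#' @export
select_spiking_units <- function(spikes, stim_window = c(0.25, 0.75),
                                 min_rate = 1) {
  stopifnot(inherits(spikes, "spike_set"))
  if (!length(spikes$units)) stop("empty spike set")
  keep <- vapply(spikes$units, function(u) {
    rates <- vapply(u, unit_condition_rate, numeric(1),
                    window = stim_window)
    any(rates >= min_rate)
  }, logical(1))
  names(spikes$units)[keep]
}

#' Normalized firing-rate tuning and time courses
#'
#' Computes trial-averaged binned rate time courses per unit and
#' condition (moving-average smoothed), normalizes each unit's time
#' courses by its global maximum over time and conditions, and derives a
#' per-condition scalar tuning value.  With `scalar = "condition_mean"`
#' (default) the scalar is the mean stimulus-window rate per condition
#' (unbinned counts) divided by the unit's maximum across conditions;
#' with `scalar = "timecourse_max"` the per-condition stimulus-window
#' mean of the globally max-normalized time course is used instead.
#'
#' @param spikes A [spike_set()].
#' @param units Unit names to process (default: all, typically the output
#'   of [select_spiking_units()]).
#' @param bin_ms Rate bin width in ms (default 10).
#' @param smooth_ms Moving-average smoothing window in ms (default 50).
#' @param stim_window Stimulus window in seconds (default
#'   `c(0.25, 0.75)`).
#' @param scalar Scalar-tuning convention, see above.
#' @return List of class `normalized_tuning`: `tuning` (units x
#'   conditions matrix, per-unit maximum exactly 1), `timecourses`
#'   (list per unit of conditions x bins matrices, max-normalized),
#'   `bin_centers` (s), `scalar`.
#' @export
normalized_rates <- function(spikes, units = NULL, bin_ms = 10,
                             smooth_ms = 50, stim_window = c(0.25, 0.75),
                             scalar = c("condition_mean",
                                        "timecourse_max")) {
  stopifnot(inherits(spikes, "spike_set"))
  scalar <- match.arg(scalar)
  if (is.null(units)) units <- names(spikes$units)
  ncond <- nrow(spikes$conditions)
  breaks <- seq(spikes$t_range[1], spikes$t_range[2], by = bin_ms / 1000)
  centers <- breaks[-length(breaks)] + bin_ms / 2000
  ksmooth <- max(1L, round(smooth_ms / bin_ms))
  kernel <- rep(1 / ksmooth, ksmooth)

  tuning <- matrix(NA_real_, length(units), ncond,
                   dimnames = list(units, NULL))
  timecourses <- vector("list", length(units))
  names(timecourses) <- units
  for (u in units) {
    tc <- matrix(0, ncond, length(centers))
    means <- numeric(ncond)
    for (cc in seq_len(ncond)) {
      trials <- spikes$units[[u]][[cc]]
      ntr <- length(trials)
      if (!ntr) next
      cnt <- tabulate(findInterval(unlist(trials), breaks,
                                   rightmost.closed = TRUE),
                      nbins = length(centers))
      rate <- cnt / ntr / (bin_ms / 1000)
      sm <- stats::filter(rate, kernel, sides = 2)
      sm[is.na(sm)] <- 0
      tc[cc, ] <- as.numeric(sm)
      means[cc] <- unit_condition_rate(trials, stim_window)
    }
    gmax <- max(tc)
    if (gmax <= 0) stop("unit '", u, "' has zero global maximum rate")
    tc_norm <- tc / gmax
    timecourses[[u]] <- tc_norm
    vals <- if (scalar == "condition_mean") {
      if (max(means) <= 0)
        stop("unit '", u, "' has zero stimulus-window rate everywhere")
      means / max(means)
    } else {
      sel <- centers >= stim_window[1] & centers <= stim_window[2]
      v <- rowMeans(tc_norm[, sel, drop = FALSE])
      v / max(v)
    }
    tuning[u, ] <- vals
  }
  structure(list(tuning = tuning, timecourses = timecourses,
                 bin_centers = centers, scalar = scalar),
            class = "normalized_tuning")
}

#' Regression of a normalized value on discontinuity magnitude
#'
#' Ordinary least-squares slope of the per-condition normalized values on
#' the discontinuity magnitudes (degrees of visual angle, orientation or
#' phase).
#'
#' @param values Per-condition normalized values.
#' @param magnitudes Strictly increasing discontinuity magnitudes, same
#'   length as `values`, at least 3 points.
#' @return List of class `regression_result`: `slope` (units/degree),
#'   `intercept`, `n`.
#' @examples
#' discontinuity_regression(c(1, 0.8, 0.6), c(0, 0.1, 0.2))
#' @export
discontinuity_regression <- function(values, magnitudes) {
  stopifnot(is.numeric(values), is.numeric(magnitudes),
            length(values) == length(magnitudes))
  if (length(values) < 3) stop("need at least 3 points")
  if (is.unsorted(magnitudes, strictly = TRUE))
    stop("magnitudes must be strictly increasing")
  fit <- stats::lm(values ~ magnitudes)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(values)), class = "regression_result")
}

#' Two-sided discontinuity regression
#'
#' For symmetric condition layouts (e.g. orientation differences
#' -50..+50 degrees, or phase approached from both directions), fits a
#' one-sided OLS of the normalized values on the magnitude separately for
#' each sign over a stated subrange, and reports the per-side slopes and
#' the magnitude of slope averaged across the two sides.  Zero-magnitude
#' conditions enter both sides.
#'
#' @param values Per-condition normalized values.
#' @param magnitudes Signed magnitudes, same length.
#' @param range Use only conditions with `|magnitude| <= range` (default:
#'   all).
#' @return List of class `two_sided_regression`: `slope_neg`,
#'   `slope_pos` (each on \|magnitude\|), `mean_abs_slope`, `n_neg`,
#'   `n_pos`.
#' @export
two_sided_regression <- function(values, magnitudes, range = Inf) {
  stopifnot(length(values) == length(magnitudes))
  keep <- abs(magnitudes) <= range
  values <- values[keep]; magnitudes <- magnitudes[keep]
  fit_side <- function(sel) {
    if (sum(sel) < 3) stop("missing side: need at least 3 points per side")
    x <- abs(magnitudes[sel]); y <- values[sel]
    ord <- order(x)
    discontinuity_regression(y[ord], x[ord])$slope
  }
  s_neg <- fit_side(magnitudes <= 0)
  s_pos <- fit_side(magnitudes >= 0)
  structure(list(slope_neg = s_neg, slope_pos = s_pos,
                 mean_abs_slope = mean(c(abs(s_neg), abs(s_pos))),
                 n_neg = sum(magnitudes <= 0), n_pos = sum(magnitudes >= 0)),
            class = "two_sided_regression")
}

#' Paired comparison of per-site values
#'
#' Wilcoxon signed-rank (default; exact for n <= 25 without ties, normal
#' approximation with continuity correction otherwise, zero differences
#' dropped) or two-sided paired t test.  Used both for
#' condition-versus-condition normalized values and for comparing
#' \|slope\| of gamma power versus firing rate across sites.
#'
#' @param values_a,values_b Equal-length paired samples.
#' @param test `"signed_rank"` (default) or `"t_two_sided"`.
#' @return List of class `paired_test_result`: `statistic` (z value for
#'   the signed rank, t value for the t test), `p_value`, `n` (pairs used),
#'   `test_name`, and `all_zero` (TRUE when every difference is zero, in
#'   which case `p_value = 1` by convention).
#' @export
paired_comparison <- function(values_a, values_b,
                              test = c("signed_rank", "t_two_sided")) {
  test <- match.arg(test)
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) == length(values_b))
  d <- values_a - values_b
  if (all(d == 0))
    return(structure(list(statistic = 0, p_value = 1,
                          n = length(d), test_name = test,
                          all_zero = TRUE),
                     class = "paired_test_result"))
  if (test == "t_two_sided") {
    ht <- stats::t.test(values_a, values_b, paired = TRUE)
    return(structure(list(statistic = unname(ht$statistic),
                          p_value = ht$p.value, n = length(d),
                          test_name = test, all_zero = FALSE),
                     class = "paired_test_result"))
  }
  dnz <- d[d != 0]
  n <- length(dnz)
  if (n < 5) stop("signed-rank comparison needs at least 5 non-zero pairs")
  ties <- any(duplicated(abs(dnz)))
  ht <- suppressWarnings(
    stats::wilcox.test(dnz, exact = (n <= 25 && !ties), correct = TRUE))
  V <- unname(ht$statistic)
  r <- rank(abs(dnz))
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                sum(tie_tab^3 - tie_tab) / 48)
  z <- (V - mu) / sigma
  structure(list(statistic = z, p_value = ht$p.value, n = n,
                 test_name = test, V = V, all_zero = FALSE),
            class = "paired_test_result")
}
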