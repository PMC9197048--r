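#' Population transfer-function parameters
#'
#' Parameters of the sigmoid transforming total synaptic drive into the
#' population response: the slope (gain) `m` and the half-activation
#' threshold `theta`.
#'
#' @param gain Sigmoid slope `m` (unitless), must be positive.
#' @param threshold Half-activation input `theta` (input units), must be
#'   non-negative.
#' @return An object of class `population_params`.
#' @examples
#' population_params(1, 5)
#' @export
population_params <- function(gain, threshold) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain),
            is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  if (gain <= 0) stop("sigmoid gain must be > 0")
  if (threshold < 0) stop("sigmoid threshold must be >= 0")
  structure(list(gain = gain, threshold = threshold),
            class = "population_params")
}

#' Sigmoid population response
#'
#' The offset logistic transfer function
#' \deqn{f(x) = \frac{1}{1 + e^{-m(x-\theta)}} - \frac{1}{1 + e^{m\theta}},}
#' chosen so that zero drive maps to zero response.  Its range is
#' `[-1/(1+exp(m*theta)), 1 - 1/(1+exp(m*theta)))`.
#'
#' @param drive Synaptic drive (input units); any numeric vector, must be
#'   finite.
#' @param pop A [population_params()] object.
#' @return Response values, same length as `drive`.
#' @examples
#' sigmoid_response(0, population_params(1, 5))    # exactly 0
#' sigmoid_response(10, population_params(1, 5))   # ~0.98661
#' @export
sigmoid_response <- function(drive, pop) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.numeric(drive) || any(!is.finite(drive)))
    stop("drive must be finite numeric")
  m <- pop$gain; th <- pop$threshold
  1 / (1 + exp(-m * (drive - th))) - 1 / (1 + exp(m * th))
}

#' First derivative of the sigmoid response with respect to drive
#'
#' @inheritParams sigmoid_response
#' @return Slope values (positive everywhere).
#' @export
sigmoid_slope <- function(drive, pop) {
  stopifnot(inherits(pop, "population_params"))
  m <- pop$gain; th <- pop$threshold
  s <- 1 / (1 + exp(-m * (drive - th)))
  m * s * (1 - s)
}

#' Second derivative (curvature) of the sigmoid response
#'
#' Positive below threshold (locally supralinear), negative above it
#' (locally sublinear), zero at the inflection `drive == theta`.
#'
#' @inheritParams sigmoid_response
#' @return Curvature values.
#' @export
sigmoid_curvature <- function(drive, pop) {
  stopifnot(inherits(pop, "population_params"))
  m <- pop$gain; th <- pop$threshold
  s <- 1 / (1 + exp(-m * (drive - th)))
  m^2 * s * (1 - s) * (1 - 2 * s)
}

#' Inverse of the sigmoid response
#'
#' Maps a response value back to the unique drive producing it.  Defined
#' only strictly inside the sigmoid's range.
#'
#' @param value Response value(s) strictly inside the sigmoid range.
#' @inheritParams sigmoid_response
#' @return Drive values.
#' @export
sigmoid_inverse <- function(value, pop) {
  stopifnot(inherits(pop, "population_params"))
  m <- pop$gain; th <- pop$threshold
  off <- 1 / (1 + exp(m * th))
  s <- value + off
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("value outside the open sigmoid range")
  th - log(1 / s - 1) / m
}

#' Range of the sigmoid response
#'
#' @inheritParams sigmoid_response
#' @return Numeric length-2 vector `c(lower, upper)`; the response lies in
#'   `[lower, upper)`.
#' @export
sigmoid_range <- function(pop) {
  stopifnot(inherits(pop, "population_params"))
  off <- 1 / (1 + exp(pop$gain * pop$threshold))
  c(-off, 1 - off)
}
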