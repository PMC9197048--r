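#' Connection gains of the E-I network
#'
#' Base synaptic gains `Wee, Wei, Wie, Wii` together with the lateral
#' recurrent gains `WeELR, WeILR, WiELR, WiILR` contributed by nearby
#' local recurrent networks in the hypercolumn.  Effective weights are
#' their pathway-wise sums (see [effective_weights()]).
#'
#' @param Wee,Wei,Wie,Wii Base gains (unitless, non-negative).
#' @param WeELR,WeILR,WiELR,WiILR Lateral recurrent gains (unitless,
#'   non-negative).
#' @return An object of class `connection_gains`.
#' @export
connection_gains <- function(Wee = 16, Wei = 26, Wie = 20, Wii = 1,
                             WeELR = 0, WeILR = 0, WiELR = 0, WiILR = 0) {
  g <- list(Wee = Wee, Wei = Wei, Wie = Wie, Wii = Wii,
            WeELR = WeELR, WeILR = WeILR, WiELR = WiELR, WiILR = WiILR)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("gain '", nm, "' must be a single finite non-negative number")
  }
  structure(g, class = "connection_gains")
}

#' Effective synaptic weights
#'
#' Folds the lateral recurrent gains into effective pathway weights:
#' `wee = Wee + WeELR`, `wei = Wei + WeILR`, `wie = Wie + WiELR`,
#' `wii = Wii + WiILR`.
#'
#' @param gains A [connection_gains()] object or an `ei_model_spec`.
#' @return Named list with elements `wee`, `wei`, `wie`, `wii`.
#' @examples
#' effective_weights(connection_gains())  # defaults: 16, 26, 20, 1
#' @export
effective_weights <- function(gains) {
  if (inherits(gains, "ei_model_spec")) gains <- gains$gains
  stopifnot(inherits(gains, "connection_gains"))
  list(wee = gains$Wee + gains$WeELR,
       wei = gains$Wei + gains$WeILR,
       wie = gains$Wie + gains$WiELR,
       wii = gains$Wii + gains$WiILR)
}

#' E-I network model specification
#'
#' Bundles the transfer-function parameters of both populations, the
#' connection gains, and the population time constants.  The defaults are
#' the canonical parameter set `wee = 16, wei = 26, wie = 20, wii = 1,
#' mE = mI = 1, thetaE = 5, thetaI = 20, tauE = 20 ms, tauI = 10 ms`,
#' which places the network in an inhibition-stabilized regime with
#' gamma-band limit cycles for suitable external drive.
#'
#' @param gains A [connection_gains()] object.
#' @param e_params,i_params [population_params()] for the excitatory and
#'   inhibitory populations.
#' @param tauE,tauI Time constants in milliseconds (positive).
#' @return An object of class `ei_model_spec`.
#' @examples
#' spec <- ei_model_spec()
#' effective_weights(spec)
#' @export
ei_model_spec <- function(gains = connection_gains(),
                          e_params = population_params(1, 5),
                          i_params = population_params(1, 20),
                          tauE = 20, tauI = 10) {
  stopifnot(inherits(gains, "connection_gains"),
            inherits(e_params, "population_params"),
            inherits(i_params, "population_params"),
            is.numeric(tauE), length(tauE) == 1L, is.finite(tauE), tauE > 0,
            is.numeric(tauI), length(tauI) == 1L, is.finite(tauI), tauI > 0)
  structure(list(gains = gains, e_params = e_params, i_params = i_params,
                 taus = c(tauE = tauE, tauI = tauI)),
            class = "ei_model_spec")
}

#' @export
print.ei_model_spec <- function(x, ...) {
  w <- effective_weights(x)
  cat("E-I network model\n")
  cat(sprintf("  effective weights: wee=%.4g wei=%.4g wie=%.4g wii=%.4g\n",
              w$wee, w$wei, w$wie, w$wii))
  cat(sprintf("  E sigmoid: m=%.4g theta=%.4g | I sigmoid: m=%.4g theta=%.4g\n",
              x$e_params$gain, x$e_params$threshold,
              x$i_params$gain, x$i_params$threshold))
  cat(sprintf("  time constants: tauE=%.4g ms, tauI=%.4g ms\n",
              x$taus[["tauE"]], x$taus[["tauI"]]))
  invisible(x)
}

#' Model a stimulus discontinuity as a reduction of an effective weight
#'
#' A discontinuity between the receptive-field center and its surround
#' removes part of the lateral recurrent drive, which in the lumped model
#' amounts to scaling down an effective weight.  The named pathway's base
#' and lateral gains are both multiplied by `scale`, so the effective
#' weight scales exactly by `scale`; everything else is untouched and the
#' input spec is not modified.
#'
#' @param spec An [ei_model_spec()].
#' @param weight_name One of `"wee"`, `"wei"`, `"wie"`, `"wii"`.
#' @param scale Multiplier in `[0, 1]` (1 = no discontinuity).
#' @return A new `ei_model_spec`.
#' @examples
#' apply_discontinuity(ei_model_spec(), "wee", 0.9)  # wee: 16 -> 14.4
#' @export
apply_discontinuity <- function(spec, weight_name, scale) {
  stopifnot(inherits(spec, "ei_model_spec"))
  if (!is.character(weight_name) || length(weight_name) != 1L ||
      !weight_name %in% c("wee", "wei", "wie", "wii"))
    stop("weight_name must be one of 'wee', 'wei', 'wie', 'wii'")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale < 0 || scale > 1)
    stop("scale must be a single number in [0, 1]")
  pair <- switch(weight_name,
                 wee = c("Wee", "WeELR"),
                 wei = c("Wei", "WeILR"),
                 wie = c("Wie", "WiELR"),
                 wii = c("Wii", "WiILR"))
  g <- unclass(spec$gains)
  g[pair] <- lapply(g[pair], function(v) max(0, v * scale))
  spec$gains <- do.call(connection_gains, g)
  spec
}
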