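# Steady-state residuals of the rate equations (time constants drop out):
#   g1 = -E + fE(wee*E - wei*I + iE)
#   g2 = -I + fI(wie*E - wii*I + iI)
ei_residual <- function(spec, E, I, iE, iI) {
  w <- effective_weights(spec)
  list(g1 = -E + sigmoid_response(w$wee * E - w$wei * I + iE, spec$e_params),
       g2 = -I + sigmoid_response(w$wie * E - w$wii * I + iI, spec$i_params))
}

#' Jacobian of the E-I dynamics at a state
#'
#' Analytical 2x2 Jacobian of the rate equations (including the time
#' constants), using the closed-form sigmoid derivative:
#' `[[(-1 + wee fE')/tauE, -wei fE'/tauE], [wie fI'/tauI, (-1 - wii fI')/tauI]]`.
#'
#' @param spec An [ei_model_spec()].
#' @param E,I State at which to linearize.
#' @param iE,iI External inputs.
#' @return 2x2 numeric matrix (units 1/ms).
#' @export
ei_jacobian <- function(spec, E, I, iE, iI) {
  w <- effective_weights(spec)
  tauE <- spec$taus[["tauE"]]; tauI <- spec$taus[["tauI"]]
  dE <- sigmoid_slope(w$wee * E - w$wei * I + iE, spec$e_params)
  dI <- sigmoid_slope(w$wie * E - w$wii * I + iI, spec$i_params)
  matrix(c((-1 + w$wee * dE) / tauE, w$wie * dI / tauI,
           -w$wei * dE / tauE, (-1 - w$wii * dI) / tauI),
         nrow = 2)
}

classify_eigen <- function(ev, marginal_tol = 1e-8) {
  re <- Re(ev); im <- Im(ev)
  if (all(abs(im) < 1e-12) && prod(re) < 0) return("saddle")
  if (max(abs(re)) < marginal_tol) return("marginal")
  focus <- any(abs(im) > 1e-12)
  if (max(re) > 0) if (focus) "unstable_focus" else "unstable_node"
  else if (focus) "stable_focus" else "stable_node"
}

#' Find all fixed points of the E-I network
#'
#' Multi-start damped Newton iteration on the steady-state system from an
#' `n_seed x n_seed` grid of seeds spanning the sigmoid ranges, vectorized
#' across seeds.  Converged roots are deduplicated and classified by the
#' eigenvalues of the analytical linearization.
#'
#' @param spec An [ei_model_spec()].
#' @param iE,iI External inputs.
#' @param n_seed Seeds per axis (default 50).
#' @param tol Newton step tolerance (default 1e-12).
#' @param dedupe_tol Roots closer than this (sup-norm) are merged
#'   (default 1e-6).
#' @param marginal_tol Absolute bound below which an eigenvalue real part
#'   is treated as marginal (default 1e-8).
#' @return data.frame with columns `E`, `I`, `re` (largest eigenvalue
#'   real part, 1/ms), `im` (its imaginary part magnitude), `stability`
#'   (one of stable_node, stable_focus, unstable_focus, unstable_node,
#'   saddle, marginal), and `residual`.  Zero rows (with a warning) if no
#'   seed converged.
#' @examples
#' find_fixed_points(ei_model_spec(), iE = 3, iI = 7.5)
#' @export
find_fixed_points <- function(spec, iE, iI, n_seed = 50, tol = 1e-12,
                              dedupe_tol = 1e-6, marginal_tol = 1e-8) {
  stopifnot(inherits(spec, "ei_model_spec"),
            is.finite(iE), is.finite(iI), n_seed >= 2)
  w <- effective_weights(spec)
  rE <- sigmoid_range(spec$e_params); rI <- sigmoid_range(spec$i_params)
  seeds <- expand.grid(E = seq(rE[1], rE[2], length.out = n_seed),
                       I = seq(rI[1], rI[2], length.out = n_seed))
  E <- seeds$E; I <- seeds$I
  resnorm <- function(E, I) {
    g <- ei_residual(spec, E, I, iE, iI)
    abs(g$g1) + abs(g$g2)
  }
  n0 <- resnorm(E, I)
  active <- seq_along(E)
  for (it in seq_len(100)) {
    aE <- E[active]; aI <- I[active]
    g <- ei_residual(spec, aE, aI, iE, iI)
    dEs <- sigmoid_slope(w$wee * aE - w$wei * aI + iE, spec$e_params)
    dIs <- sigmoid_slope(w$wie * aE - w$wii * aI + iI, spec$i_params)
    j11 <- -1 + w$wee * dEs; j12 <- -w$wei * dEs
    j21 <- w$wie * dIs;      j22 <- -1 - w$wii * dIs
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- NA
    s1 <- (-j22 * g$g1 + j12 * g$g2) / det
    s2 <- ( j21 * g$g1 - j11 * g$g2) / det
    s1[is.na(s1)] <- 0; s2[is.na(s2)] <- 0
    lam <- rep(1, length(aE))
    En <- aE + s1; In <- aI + s2
    n1 <- resnorm(En, In)
    a0 <- n0[active]
    for (h in seq_len(40)) {
      bad <- which(!(n1 <= a0) & lam > 1e-8)
      if (!length(bad)) break
      lam[bad] <- lam[bad] / 2
      En[bad] <- aE[bad] + lam[bad] * s1[bad]
      In[bad] <- aI[bad] + lam[bad] * s2[bad]
      n1[bad] <- resnorm(En[bad], In[bad])
    }
    step <- pmax(abs(lam * s1), abs(lam * s2))
    E[active] <- En; I[active] <- In; n0[active] <- n1
    # retire seeds that have converged (or stalled at the damping floor)
    done <- step < tol | (lam <= 2e-8 & n1 > 1e-9)
    active <- active[!done]
    if (!length(active)) break
  }
  ok <- which(is.finite(n0) & n0 < 1e-9)
  if (!length(ok)) {
    warning("no Newton seed converged to a fixed point")
    return(data.frame(E = numeric(0), I = numeric(0), re = numeric(0),
                      im = numeric(0), stability = character(0),
                      residual = numeric(0)))
  }
  E <- E[ok]; I <- I[ok]
  ord <- order(E, I)
  E <- E[ord]; I <- I[ord]
  keepE <- numeric(0); keepI <- numeric(0)
  for (r in seq_along(E)) {
    if (!length(keepE) ||
        all(pmax(abs(keepE - E[r]), abs(keepI - I[r])) > dedupe_tol)) {
      keepE <- c(keepE, E[r]); keepI <- c(keepI, I[r])
    }
  }
  res <- vapply(seq_along(keepE), function(r) {
    g <- ei_residual(spec, keepE[r], keepI[r], iE, iI)
    max(abs(g$g1), abs(g$g2))
  }, numeric(1))
  cls <- character(length(keepE)); re <- numeric(length(keepE))
  im <- numeric(length(keepE))
  for (r in seq_along(keepE)) {
    ev <- eigen(ei_jacobian(spec, keepE[r], keepI[r], iE, iI),
                only.values = TRUE)$values
    k <- which.max(Re(ev))
    re[r] <- Re(ev[k]); im[r] <- abs(Im(ev[k]))
    cls[r] <- classify_eigen(ev, marginal_tol)
  }
  data.frame(E = keepE, I = keepI, re = re, im = im, stability = cls,
             residual = res, stringsAsFactors = FALSE)
}

#' Brute-force fixed-point scan (reference oracle)
#'
#' Independent cross-check for [find_fixed_points()]: a dense residual
#' scan over an `n_grid x n_grid` lattice of the (E, I) plane locates
#' candidate basins, which are then refined by bisection along the
#' closed-form E-nullcline (on which every fixed point must lie).  Slower
#' than the Newton solver but algorithmically unrelated to it.
#'
#' @inheritParams find_fixed_points
#' @param n_grid Lattice points per axis (default 2000).
#' @return data.frame with columns `E`, `I`, sorted by `E`.
#' @export
fixed_points_bruteforce <- function(spec, iE, iI, n_grid = 2000) {
  stopifnot(inherits(spec, "ei_model_spec"))
  w <- effective_weights(spec)
  rE <- sigmoid_range(spec$e_params); rI <- sigmoid_range(spec$i_params)
  eps <- 1e-12
  Eg <- seq(rE[1] + eps, rE[2] - eps, length.out = n_grid)
  Ig <- seq(rI[1] + eps, rI[2] - eps, length.out = n_grid)
  dE <- Eg[2] - Eg[1]
  # every fixed point lies on the closed-form E-nullcline
  # I(E) = (wee*E + iE - fE^{-1}(E)) / wei; h(E) is the I-equation
  # residual along that curve, so roots of h are the fixed points
  h <- function(E) {
    I <- (w$wee * E + iE - sigmoid_inverse(E, spec$e_params)) / w$wei
    -I + sigmoid_response(w$wie * E - w$wii * I + iI, spec$i_params)
  }
  bisect <- function(lo, hi, hl) {
    for (b in seq_len(200)) {
      mid <- (lo + hi) / 2
      hm <- h(mid)
      if (sign(hm) == sign(hl)) { lo <- mid; hl <- hm } else hi <- mid
      if (hi - lo < 1e-14) break
    }
    (lo + hi) / 2
  }
  hg <- h(Eg)
  flips <- which(sign(hg[-n_grid]) != sign(hg[-1]))
  roots <- vapply(flips, function(j) bisect(Eg[j], Eg[j + 1], hg[j]),
                  numeric(1))
  # residual magnitude on the full lattice: candidate basins catch roots
  # that a pure sign-change scan could miss (near-tangencies)
  fe <- outer(Eg, Ig, function(E, I)
    abs(-E + sigmoid_response(w$wee * E - w$wei * I + iE, spec$e_params)))
  fi <- outer(Eg, Ig, function(E, I)
    abs(-I + sigmoid_response(w$wie * E - w$wii * I + iI, spec$i_params)))
  R <- pmax(fe, fi)
  rm(fe, fi)
  pad <- function(M, side) {
    n <- n_grid
    switch(side,
           up = rbind(M[1, ], M[-n, ]), down = rbind(M[-1, ], M[n, ]),
           left = cbind(M[, 1], M[, -n]), right = cbind(M[, -1], M[, n]))
  }
  locmin <- R <= pad(R, "up") & R <= pad(R, "down") &
            R <= pad(R, "left") & R <= pad(R, "right") & R < 0.05
  candE <- unique(Eg[which(rowSums(locmin) > 0)])
  rm(R, locmin)
  for (e0 in candE) {
    if (length(roots) && min(abs(roots - e0)) <= 3 * dE) next
    lo <- max(rE[1] + eps, e0 - 3 * dE); hi <- min(rE[2] - eps, e0 + 3 * dE)
    opt <- stats::optimize(function(x) abs(h(x)), c(lo, hi), tol = 1e-13)
    if (abs(opt$objective) < 1e-10) roots <- c(roots, opt$minimum)
  }
  roots <- sort(roots)
  keep <- numeric(0)
  for (r in roots)
    if (!length(keep) || min(abs(keep - r)) > 1e-7) keep <- c(keep, r)
  I <- if (length(keep))
    (w$wee * keep + iE - sigmoid_inverse(keep, spec$e_params)) / w$wei
  else numeric(0)
  data.frame(E = keep, I = I)
}
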