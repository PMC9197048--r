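#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Logistic transfer with the lower offset subtracted so that f(0) = 0
// when the offset is 1/(1+exp(m*theta)).
static inline double transfer(double x, double m, double th, double off) {
  return 1.0 / (1.0 + std::exp(-m * (x - th))) - off;
}

// Classical fixed-step RK4 for the two coupled rate equations
//   tauE dE/dt = -E + fE(wee*E - wei*I + iE [+ noiseE])
//   tauI dI/dt = -I + fI(wie*E - wii*I + iI [+ noiseI])
// Optional additive drive noise is held constant within each step.
// Returns E, I at the n+1 grid points and a finite-state flag; on
// numerical blow-up integration stops and `ok` is FALSE with `n_done`
// giving the last valid sample.
// [[Rcpp::export]]
List rk4_ei_core(double wee, double wei, double wie, double wii,
                 double mE, double thE, double mI, double thI,
                 double tauE, double tauI,
                 double iE, double iI,
                 int n, double dt, double E0, double I0,
                 NumericVector noiseE, NumericVector noiseI) {
  NumericVector E(n + 1), I(n + 1);
  const double offE = 1.0 / (1.0 + std::exp(mE * thE));
  const double offI = 1.0 / (1.0 + std::exp(mI * thI));
  const bool use_noise = (noiseE.size() == n && noiseI.size() == n);
  double e = E0, ii_ = I0;
  E[0] = e; I[0] = ii_;
  bool ok = true;
  int n_done = 0;

  for (int k = 0; k < n; ++k) {
    const double nE = use_noise ? noiseE[k] : 0.0;
    const double nI = use_noise ? noiseI[k] : 0.0;

#define DERIV(ei, in, de, di)                                              \
  do {                                                                     \
    de = (-(ei) + transfer(wee * (ei) - wei * (in) + iE + nE, mE, thE,     \
                           offE)) / tauE;                                  \
    di = (-(in) + transfer(wie * (ei) - wii * (in) + iI + nI, mI, thI,     \
                           offI)) / tauI;                                  \
  } while (0)

    double k1e, k1i, k2e, k2i, k3e, k3i, k4e, k4i;
    DERIV(e, ii_, k1e, k1i);
    DERIV(e + 0.5 * dt * k1e, ii_ + 0.5 * dt * k1i, k2e, k2i);
    DERIV(e + 0.5 * dt * k2e, ii_ + 0.5 * dt * k2i, k3e, k3i);
    DERIV(e + dt * k3e, ii_ + dt * k3i, k4e, k4i);
#undef DERIV

    e   += dt / 6.0 * (k1e + 2.0 * k2e + 2.0 * k3e + k4e);
    ii_ += dt / 6.0 * (k1i + 2.0 * k2i + 2.0 * k3i + k4i);
    if (!std::isfinite(e) || !std::isfinite(ii_)) { ok = false; break; }
    E[k + 1] = e; I[k + 1] = ii_;
    n_done = k + 1;
  }

  return List::create(_["E"] = E, _["I"] = I,
                      _["ok"] = ok, _["n_done"] = n_done);
}
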