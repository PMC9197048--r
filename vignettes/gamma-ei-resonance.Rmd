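---
title: "An E-I resonance model of cortical gamma and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An E-I resonance model of cortical gamma and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaEI)
```

## The model

Gamma-band oscillations (~30-80 Hz) in primary visual cortex arise from
the push-pull interaction of excitatory (E) and inhibitory (I) neural
populations.  `gammaEI` implements a lumped Wilson-Cowan-type model of
one orientation column in which the recurrent input a column receives
from neighbouring columns of the hypercolumn (its *lateral recurrent*
input) is folded into the connection weights:

$$\tau_E \dot E = -E + f_E(w_{ee}E - w_{ei}I + i_E), \qquad
  \tau_I \dot I = -I + f_I(w_{ie}E - w_{ii}I + i_I),$$

with the offset-logistic transfer function

$$f_x(u) = \frac{1}{1+e^{-m_x(u-\theta_x)}} - \frac{1}{1+e^{m_x\theta_x}},$$

so that $f_x(0)=0$ and the origin is a fixed point under zero drive.
Each effective weight is the sum of a base gain and a lateral recurrent
gain, e.g. $w_{ee} = W_{ee} + W_{eELR}$.  A *stimulus discontinuity* — a
mismatch in space, orientation, phase or contrast between the patch
covering the column's receptive field and its surround — removes part of
the coherent lateral drive.  In the lumped model this is a reduction of
an effective weight, implemented by `apply_discontinuity()`.

The default parameter set is the canonical one for this model family:
$w_{ee}=16$, $w_{ei}=26$, $w_{ie}=20$, $w_{ii}=1$, $m_E=m_I=1$,
$\theta_E=5$, $\theta_I=20$, $\tau_E=20$, $\tau_I=10$.  Time is in
**milliseconds** — the sources of this parameter set do not state a
unit, but with millisecond time constants the limit cycles fall in the
gamma range, which fixes the choice.

## Numerical choices

* **Integrator.**  Classical fixed-step RK4 (compiled), default
  `dt_ms = 0.05`; the solver refuses steps coarser than $\tau_I/50$.
  Halving the step changes trajectories by $<10^{-7}$ sup-norm over the
  standard input grid, far below the $10^{-4}$ contract asserted in the
  tests.  An adaptive LSODA integration (deSolve) serves as an
  independent oracle in the test suite.  Simulations are deterministic
  and noise-free; an additive drive-noise hook exists (`noise_sd`) but
  is off by default, because the reference behaviour of the model is the
  deterministic limit cycle.
* **Initial state and transient.**  Simulations start at the origin and
  metrics discard a transient (500-1000 ms in most analyses; 3000 ms
  where a damped condition must reach its asymptotic state).
* **Fixed points.**  `find_fixed_points()` runs a damped Newton
  iteration from a 50x50 seed grid spanning the sigmoid box, vectorized
  across seeds, deduplicates at $10^{-6}$ and classifies each root by
  the eigenvalues of the analytical Jacobian (closed-form sigmoid
  derivative, never finite differences).  `fixed_points_bruteforce()`
  is the deliberately unrelated oracle: a dense lattice residual scan
  plus bisection along the closed-form E-nullcline.  Eigenvalue real
  parts within $10^{-8}$ of zero are labelled *marginal* and treated as
  non-oscillatory.
* **Oscillation metrics.**  Frequency comes from the mean
  upward-zero-crossing interval of the mean-subtracted E series
  (sub-sample interpolation); it is cross-checked against the
  periodogram argmax, which must agree within one Rayleigh bin for
  sustained cycles.  Peak power is the maximum of a Hann-windowed,
  4x zero-padded periodogram in the 10-150 Hz search range; the
  windowing suppresses scalloping so that power varies smoothly across
  parameter sweeps.  *Sustained* means: median per-cycle peak-to-trough
  amplitude above $10^{-3}$ activity units **and** amplitude change
  below 5% between the last two 500 ms half-windows.
* **Regime labels.**  The closed-form regime conditions in the
  literature on this model are not restated in our sources, so
  `classify_regime()` substitutes a local-curvature criterion: the E
  response is *sublinear* when $f_E''$ at the fixed-point drive is
  negative (drive above threshold), the I response *superlinear* when
  $f_I''$ there is positive.  `oscillatory` is decided empirically by
  simulation.  The regime boundary so obtained need not coincide
  quantitatively with the analytical one; all regime-dependent claims
  are therefore tested *within* flagged cells, never on the boundary.
* **Hopf scan.**  `hopf_scan()` follows the operating fixed-point
  branch along $i_I$ (Newton continuation with a global-root fallback,
  anchored by a short simulation), locates the eigenvalue zero
  crossing, and then simulates around it with 20 s of model time per
  point — settling onto a near-Hopf limit cycle is slow
  ($\propto 1/\mu$), so short simulations would misplace the onset.
  Supercriticality is declared when the amplitude grows strictly and
  continuously from zero over the first five sustained steps.
* **Input-plane maps.**  Default acceptance-scale grid:
  $i_E \in [1,10]$ step 1, $i_I \in [5.5,10]$ step 0.5 (axes fully
  configurable).  The *size* analogue is an $i_I$ increase at fixed
  $i_E$ (the surround drives inhibition).  The *contrast* analogue
  raises both drives with the excitatory drive moving twice as fast
  (contrast strengthens the center drive at least as much as the
  surround); along that direction the peak frequency rises throughout
  the flagged regime, whereas a 1:1 diagonal lets the frequency-lowering
  effect of $i_I$ cancel the rise in places.
* **Fixed-point shift.**  The perturbation experiment reports
  $\lVert\Delta(E^*,I^*)\rVert_2 / \lVert(E^*,I^*)\rVert_2$.  A
  componentwise definition would be dominated by the small $I^*$
  denominator and overstate how much the operating point moves.

## The LFP spectral pipeline

Spectra are single-taper estimates: one Slepian (DPSS) taper with
time-bandwidth product 1, computed from the standard tridiagonal
eigenproblem — a 0.25 s window then has 4 Hz resolution.  A
split-cosine tapered periodogram is available as a fallback and agrees
within 1 dB on the ratio-calibration suite (tested).  Conventions:

* Sliding-window difference spectra (`tf_difference_spectrum()`):
  0.25 s windows, 25 ms step (the step is our choice; the window and
  resolution are fixed by the method).  Powers are averaged across
  trials *before* the log; the mean log-spectrum over baseline windows
  (centers in −0.5-0 s) is subtracted per frequency; x10 gives decibel.
* Change in power (`change_in_power()`): single-taper PSDs over
  0.25-0.75 s (stimulus) versus −0.5-0 s (baseline); both windows are
  0.5 s so bins align, and they can never overlap.
* Band power is the **sum** of PSD values over bins with
  `lo <= f <= hi`, edges inclusive.  Gamma bands follow the standard
  convention (35-65 Hz, or 45-75 Hz for the second-animal convention);
  when *both* the inner and outer grating contrasts are below 100% the
  band shifts 5 Hz lower (`select_gamma_band()`).
* Per-site normalization divides per-condition band powers by their
  maximum, so the maximum is exactly 1 and the operation is idempotent.
* Per-window mean removal is the only detrending; there is no mains
  notch (the synthetic data carry no line component), and the
  sub-8 Hz bins of a demeaned 0.25 s window are not interpretable.
* The per-condition gamma **peak frequency** is the in-band argmax of
  the change-in-power spectrum, reported with a `detected` flag.  With
  20 trials the no-change spectrum has a per-bin SD of ~1.4 dB and the
  maximum over the ~16 in-band bins reaches 5.3 dB at its empirical
  99.9th percentile, so the detection floor is 6 dB: a condition whose
  gamma is abolished has no defined peak frequency, and frequency-trend
  statements apply to detected conditions only.

## Spiking statistics

Units enter the analysis when their mean stimulus-window (0.25-0.75 s)
rate reaches 1 spike/s in at least one condition (boundary inclusive).
Rate time courses use 10 ms bins smoothed by a 50 ms moving average and
are normalized per unit by the global maximum over time and conditions.
The scalar per-condition tuning divides stimulus-window means by the
per-unit maximum across conditions; an alternative convention
(stimulus-window mean of the globally max-normalized time course) is
implemented because the two readings are both defensible —
`condition_mean` is the default.  Regression slopes are unweighted OLS
per site; two-sided layouts (orientation, phase) are fitted per side on
|magnitude| over a configurable subrange (defaults 0-20 deg or
0-30 deg for orientation, 0-180 deg for phase) and the slope magnitudes
averaged.  The paired signed-rank test wraps `wilcox.test`: exact for
n <= 25 without ties, normal approximation with continuity correction
otherwise, zero differences dropped, all-zero input returning p = 1 by
convention; the reported statistic is the z value.  Full enumeration
over the $2^n$ sign assignments is kept in the test suite as the
independent oracle.

## Receptive-field mapping

The evoked response of a site is the minimum trial-averaged LFP in
40-100 ms after onset minus the minimum in −100 to −40 ms.  `fit_rf()`
fits an axis-aligned 2D Gaussian (baseline + amplitude) to the
*magnitude* of the responses on the mapping grid by Levenberg-Marquardt
with moment-based starts; "RF size" is the geometric mean of the two
SDs (the literature's size definition is not restated in our sources,
so this summary is our choice; rotation is deliberately omitted).
Center sites are those within 0.2 deg (or 0.15 deg) of the stimulus
center, boundary inclusive.  The synthetic 9x9 mapping grid uses a
0.1 deg pitch for a 0.25 deg RF — about $\sigma/2.5$, the sampling a
well-designed mapping experiment would use.  At signal-to-noise 5
(peak amplitude / response noise SD) the Cramér-Rao bound for the
center is ~0.017 deg per axis, so the 0.05 deg recovery contract is
demanding but attainable; with a coarser 0.25 deg pitch it would be
impossible for any estimator, which is worth remembering when applying
the fit to real mapping grids.

## The synthetic-session generator

`generate_session()` emulates the *statistical structure* the pipeline
assumes, with every programmed law stored as ground truth:

* trials of 2 s at 2 kHz (onset at 0, stimulus 0-0.8 s, >= 0.5 s
  baseline);
* 1/f baseline noise (spectrally shaped white noise, $\beta = 1$);
* an induced gamma component only during the stimulus epoch: amplitude
  $A_0 e^{-d/\lambda}$ and frequency $f_0 + k d$ for discontinuity
  magnitude $d$, with a random phase per trial (induced, not
  phase-locked) and 50 ms raised-cosine ramps;
* inhomogeneous-Poisson spiking: baseline 5 spikes/s, stimulus rate
  $r_0(1 + s d)$ with $r_0 = 20$, $s = 1$/deg — a modest *increase*
  with discontinuity, deliberately opposite in sign to the gamma
  attenuation — scaled per unit by a lognormal heterogeneity factor
  (sdlog 0.3) so that rate effects vary across units while gamma
  attenuation is uniform.

Defaults: annulus widths $\{0, 0.025, 0.05, 0.1, 0.2\}$ deg, 20 trials,
8 units, $\lambda = 0.1$ deg, $f_0 = 50$ Hz, $k = 20$ Hz/deg, and
$A_0 = 1.25$, which calibrates the in-band signal-to-noise ratio to
about 10 dB over the default noise.  Identical configuration and seed
give byte-identical sessions.  The attenuation constant is recovered
from baseline-subtracted band powers via
$\log(\text{power}) \sim d$, $\hat\lambda = -2/\text{slope}$ (power
goes as amplitude squared).

`generate_model_driven_session()` replaces the programmed amplitude law
by the model itself: each condition's effective weight is scaled, the
network simulated, and the post-transient mean-subtracted E trace
(resampled to 2 kHz, scaled by `component_scale = 60` so that the
intact network's oscillation sits well above the noise floor) is
injected during the stimulus epoch; trials differ by noise realization
and a random circular offset into the trace.  The model transient
discarded before resampling is 3000 ms so that *damped* conditions
contribute their asymptotic (flat) state rather than leftover
ring-down.

What the generator does **not** emulate — and hence what passing tests
do not establish about real recordings: no stimulus-locked evoked
transients in the LFP, no slow-gamma band or gamma harmonics, no mains
line, no cross-electrode correlations, no eye movements or
microsaccades, no spike-field locking, and no artifact or electrode
quality issues.  The end-to-end studies show that the *pipeline*
recovers what was programmed, not that cortex behaves like the
generator.

## Study problem sizes

The packaged studies use: 100 randomized parameter sets against a
2000x2000 brute-force scan; a 201-point Hopf sweep (step 0.1) with 20 s
simulations near onset; a 10x10 input-plane grid; 50 + 10x30 seeded
sessions for the recovery and replicate-significance studies; 200 RF
grids; and full sign-assignment enumeration up to n = 10 for the
signed-rank oracle.  `scripts/acceptance.R` re-runs all of these from
scratch and writes the resulting numbers as JSON.

## Known limitations

The lumped model has no spatial structure (lateral columns exist only
inside the weights), so discontinuity *geometry* cannot be represented,
only its net effect on the weights; the mapping from physical
discontinuity magnitude to weight scale is a free monotone function.
The curvature-based regime boundary is a local criterion and can
disagree with the analytical one near its edges.  Gamma "power" from
the model is the periodogram peak of a noise-free limit cycle, an
arbitrary-units quantity meaningful only in ratios.  The signed-rank
exact path requires tie-free differences; ties fall back to the normal
approximation.  All LFP units are arbitrary: only decibel ratios are
interpreted.
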