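# gammaEI

Visual cortical gamma oscillations (~30-80 Hz) are strongest for large,
uniform gratings and collapse when the stimulus covering a neuron's
receptive field is separated from its surround by even a tiny
discontinuity — an annular gap, an orientation or phase mismatch, or a
contrast step.  `gammaEI` is an R package for researchers studying this
phenomenon computationally: it implements a lumped
excitatory-inhibitory (E-I) resonance model that explains the
fragility, together with the electrophysiology analysis pipeline
(LFP spectra, spiking statistics, receptive-field mapping) used to
quantify it, and seeded synthetic-session generators for end-to-end
validation of that pipeline against known ground truth.

## The model

A single orientation column is described by Wilson-Cowan-type rate
equations in which lateral recurrent input from neighbouring columns is
folded into effective weights:

    tauE dE/dt = -E + fE(wee*E - wei*I + iE)
    tauI dI/dt = -I + fI(wie*E - wii*I + iI)

with sigmoid transfer `fx(u) = 1/(1+exp(-mx(u-thetax))) - 1/(1+exp(mx*thetax))`
and `wee = Wee + WeELR` etc.  Defaults: `wee=16, wei=26, wie=20, wii=1,
mE=mI=1, thetaE=5, thetaI=20, tauE=20 ms, tauI=10 ms`.  At the standard
operating drive (`iE=3, iI=7.5`) the network sits just beyond a
supercritical Hopf bifurcation and produces a sustained ~46 Hz limit
cycle.  A stimulus discontinuity removes coherent lateral drive, i.e.
scales an effective weight down: a 20% reduction of `wee` re-stabilizes
the fixed point and abolishes the oscillation while the mean E/I
operating point moves by only ~13% — the resonance argument for why
gamma is so much more sensitive to discontinuities than firing rates.

The analysis side implements the field's standard operations:
single-Slepian-taper difference spectra (0.25 s window, 4 Hz
resolution, decibel relative to the pre-stimulus baseline), band power
as the inclusive sum of PSD bins with the 35-65 / 45-75 Hz band
conventions and the 5 Hz low-contrast shift, per-site max
normalization, firing-rate tuning with per-unit normalization,
OLS discontinuity-regression slopes, exact Wilcoxon signed-rank
comparisons, and axis-aligned 2D Gaussian receptive-field fits to 9x9
evoked-response grids.

## Worked example

Generate a synthetic session (5 annulus-width conditions, 20 trials,
8 spiking units, programmed gamma attenuation `exp(-d/0.1)`) and run
the full pipeline:

```r
library(gammaEI)
ses <- generate_session(session_config(seed = 7))
analyze_session(ses)
#> session analysis (band 35-65 Hz)
#>   magnitude stim_band_power base_band_power delta_band_power norm_gamma
#> 1     0.000        891.3435         75.9142         815.4293     1.0000
#> 2     0.025        509.1111         79.3987         429.7124     0.5712
#> 3     0.050        368.5359         70.2889         298.2470     0.4135
#> 4     0.100        180.3038         83.4050          96.8988     0.2023
#> 5     0.200         87.0368         82.4660           4.5708     0.0976
#>   peak_freq peak_db detected
#> 1        50 21.6775        1
#> 2        50 17.6685        1
#> 3        52 13.9731        1
#> 4        52 12.7995        1
#> 5        54  5.3512        0
#> gamma slope: -3.865 /deg | rate slope: 0.8723 /deg (8 units)
```

Reading the table: normalized gamma power falls monotonically with the
discontinuity magnitude (column `norm_gamma`; the 0.2-degree condition
retains ~10% of the intact power), the gamma peak frequency drifts
upward (50 to 54 Hz; the weakest condition falls below the 6 dB
detection floor), and the regression slope of normalized gamma on
magnitude (-3.9 per degree) is more than four times steeper than the
firing-rate slope (+0.87 per degree) — gamma is the far more sensitive
discontinuity signal.

On the model side:

```r
weight_perturbation_experiment(ei_model_spec(), "wee", c(1, 0.9, 0.8),
                               iE = 3, iI = 7.5)
#>   scale   peak_power peak_frequency    amplitude sustained    E_star    I_star
#> 1   1.0 1.239509e+01       45.73720 1.176122e-01      TRUE 0.5889546 0.2706120
#> 2   0.9 4.479801e+00       47.37875 6.948746e-02      TRUE 0.5758108 0.2291775
#> 3   0.8 5.311096e-07       46.41541 2.053627e-05     FALSE 0.5616206 0.1889912
#>   fixed_point_shift
#> 1        0.00000000
#> 2        0.06706661
#> 3        0.13280284
```

A 10% `wee` reduction drops oscillation power to 36%, a 20% reduction
abolishes it (the fixed point turns stable), yet the operating point
barely moves.

The numbered scripts under `analysis/` run the complete studies —
phase-plane analysis, input-plane maps, the Hopf scan, the 50-session
recovery study and the RF-mapping study — and write their tables under
`results/`.

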