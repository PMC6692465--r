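# mfaim — multifractal nonlinearity analysis of aiming movement

`mfaim` quantifies *nonlinear interactions across time scales* in rhythmic
aiming movement and relates them to aiming accuracy. It is written for
movement scientists analyzing motion-capture recordings of a two-target
tapping (Fitts) task, and for methodologists who need a tested, seeded
implementation of the underlying nonlinear time-series machinery.

## What it computes

For each non-overlapping epoch of 20/40/80 movement cycles, in both the
lateral hand series and the head interpoint-distance series:

1. **Direct multifractal spectrum.** The series becomes a unit-mass
   measure binned at dyadic scales `L ∈ {4, 8, …, N/4}`. With bin
   proportions `P_i(L)` and mass weights
   `μ_i(q, L) = P_i(L)^q / Σ_j P_j(L)^q`, the singularity strength
   `α(q)` is the slope of `Σ μ_i ln P_i` on `ln L`, and `f(q)` the slope
   of `Σ μ_i ln μ_i` on `ln L`. Orders with log-log fit `|r| < 0.995`
   are excluded; the spectrum width is `W = max α(q) − min α(q)`.
2. **IAAFT surrogates.** Each epoch is compared against (by default) 30
   iterative amplitude-adjusted Fourier-transform surrogates, which keep
   the epoch's exact values and approximate amplitude spectrum while
   destroying nonlinear sequence structure.
3. **The nonlinearity statistic**
   `t_MF = (W_orig − mean W_surr) / SE_surr`, with significance called
   when `W_orig` leaves the ensemble's two-sided 95% range.
4. **Aiming variability** `SD(Aim)`: the pooled standard deviation of
   contact positions around each target's own epoch mean.
5. **A mixed-effects interaction model** of `SD(Aim)` on Expectation,
   Closedeyes, epoch number/size, half, `t_MF` and spectrum-width
   covariates (participant random intercept, `nlme`), plus bootstrap
   power analysis and an effect-range summary of the
   nonlinearity-driven predictions.

A seeded synthetic-data generator (binomial multiplicative cascades,
AR(1) nulls, and full simulated task sessions with planted condition
effects) makes every stage testable without external recordings.

## Worked example

```r
library(mfaim)

## a multifractal calibration series with a known spectrum width
x <- binomial_cascade(levels = 14, weight_p = 0.25)
sp <- cj_spectrum(x, shift_policy = "none")
sp
#> Direct multifractal spectrum: n = 16384, 11 scales (4..4096), 41/41 q retained
#>   width = 1.572

cascade_width_analytic(0.25)      # closed-form oracle
#> [1] 1.571971

## surrogate test: the cascade is strongly nonlinear ...
ens <- surrogate_ensemble(x, n_surrogates = 30, shift_policy = "none", seed = 1)
tmf_stat(sp$width, ens)
#> t_MF = 54.553 (sem mode; W_orig = 1.572, surrogate mean = 0.7612,
#>   sd = 0.08141, n = 30)
#>   significant nonlinearity (outside 95% ensemble range)

## ... a linear AR(1) series is not
y <- ar1_series(1024, phi = 0.8, seed = 2)
tmf_stat(cj_spectrum(y)$width, surrogate_ensemble(y, 30, seed = 3))
#> t_MF = -3.433 (sem mode; W_orig = 0.2212, surrogate mean = 0.2306,
#>   sd = 0.01489, n = 30)
#>   not significant

## end-to-end on simulated sessions
cfg <- pipeline_config(
  sim_params = fitts_sim_params(n_participants = 12, block_duration = 100,
                                sample_rate = 30, nonlinearity_coupling = 1,
                                expectation_shrink = 1.5, depth_sd = 1.2),
  epoch_sizes = c(10, 20), q_step = 0.5, n_surrogates = 6, max_iter = 30,
  seed = 1, out_dir = "mfaim-run")
manifest <- run_pipeline(cfg)
```

The pipeline writes, under `mfaim-run/`: `epochs.csv` (one row per epoch
with `sd_aim`, `w_hand`, `w_head`, `tmf_hand`, `tmf_head`, head
descriptives and condition labels), `coefficients.csv` (predictor /
estimate / SE / p), `model.json` (fit correlation and variance
components), `effect_range.json` (the span of nonlinearity-driven
predictions at the `t_MF` quartiles against the observed `SD(Aim)`
interquartile range) and `manifest.json`. Re-running with the same seed
reproduces every file bit-for-bit. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

The effect-range summary itself is plain arithmetic; on the reference
numbers it reads:

```r
summarize_effect_range(c(-0.0025, 0.0035),
                       observed_quartiles = c(0.0131, 0.0194))
#> $predicted_range
#> [1] 0.006
#> $observed_iqr
#> [1] 0.0063
#> $coverage_pct
#> [1] 95.2381
#> $flagged
#> [1] FALSE
```

i.e. the middle 50% of the nonlinearity estimates spans about 95% of the
middle 50% of observed epoch-by-epoch aiming variability.

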