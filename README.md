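# paleodem

Palaeodemographic inference from archaeological radiocarbon records.

Archaeologists use the density of radiocarbon-dated human activity as a
proxy for relative population size: under the assumption that more people
leave more datable carbon, the **summed probability distribution (SPD)** of
a region's calibrated dates tracks population through time.  Making that
proxy trustworthy takes a pipeline — quality filtering, anti-oversampling
binning, calibration, taphonomic correction, bootstrap uncertainty, and a
simulated null model to separate demography from calibration artefacts —
and interpreting it takes explicit demographic models.  `paleodem`
implements all of it for hunter-gatherer records of the Pleistocene–Holocene
transition, in base R.

## What it computes

* **Calibration engine** — reads `.14c` curve files, calibrates
  (`calibrate()`) and back-calibrates dates, builds mixed
  marine–terrestrial curves with ΔR reservoir offsets
  (`mix_curves()`, `marine_fraction_from_d13c()`), and pools replicate
  determinations by the Ward–Wilson test (`combine_equivalent()`).
* **Database preparation** — schema-validated loading with a provenance log
  (`load_dataset()`), strict error/material filters (`filter_dates()`),
  per-site 200-yr binning (`assign_bins()`), same-context pooling
  (`apply_combinations()`).
* **SPD builder** — per-bin summation (`sum_probabilities()`), taphonomic
  correction of open-air components by `a (t + b)^c` survival
  (`taphonomic_correct()`), optional consumption-scaling correction,
  composition and window trimming.
* **Resampling inference** — bootstrap ensembles with back-calibration and
  error permutation (`bootstrap_spd()`), an exponential null model
  (`fit_exponential_null()`, `simulate_null()`), departure regions and a
  rank-based global p-value (`find_departures()`, `global_pvalue()`), and
  regional subsampling nulls (`regional_null()`).
* **Growth-model selection** — six piecewise demographies (exponential,
  logistic and decay-to-limit phases; models A–F) fitted by a deterministic
  breakpoint scan and ranked by AIC/SBC (`fit_growth_models()`), with
  `print()`, `summary()`, `coef()`, `predict()`, `plot()`, `residuals()` and
  `simulate()` methods, per-phase annual growth rates (`growth_rate()`,
  `growth_rate_ci()`), `doubling_time()` and `fold_change()`.
* **Proxy correlation** — Spearman correlation of every bootstrap member
  against palaeoenvironmental series (`spearman_ensemble()`), detrended
  variance as an instability index (`detrended_variance()`).
* **Synthetic data** — scenario generator with known demographic ground
  truth (`simulate_dataset()`, `scenario_preset()`, `simulate_proxy()`), so
  every estimator is testable offline.
* **Pipeline** — `run_stage()` / `run_pipeline()` drive the whole analysis
  from a YAML config into versioned CSV/JSON artifacts with manifests; a
  thin CLI wrapper lives at `inst/cli/paleodem.R`.

## The model at the core

The population proxy is fitted, over the analysis window, by piecewise
models in forward time τ (years since the window's old edge):
exponential phases `α e^{rτ}`, decay-to-limit phases `a e^{-bτ} + c`, and
logistic phases `A / (1 + e^{(x₀-τ)/s}) + c`.  Breakpoints are scanned in
1-year steps within ±150 yr of climatic anchors (defaults: Younger Dryas
onset 12.9 kya, Early Mesolithic onset 10.2 kya), each phase must last
≥ 2000 yr, and models are ranked by `AIC = n ln(RSS/n) + 2k` and
`SBC = n ln(RSS/n) + k ln n` with every scanned breakpoint counted in `k`.
Annual growth rates are `100 (y(τ+1)/y(τ) − 1)` %.

## Worked example

Fit the six models to a noiseless proxy generated from a three-phase
(model F) demography with breakpoints at 12,780 and 10,120 cal BP:

```r
library(paleodem)

r1 <- log(1 + 0.0411 / 100)                      # phase-1 rate, 0.0411 %/yr
y1 <- exp(r1 * 5220); y2 <- 0.5 * y1
truth <- list(phases = c("exponential", "decay_to_limit", "logistic"),
              params = list(c(alpha = 1, rate = r1),
                            c(a = 0.5 * y1, b = 0.0158, c = 0.5 * y1),
                            c(A = y2, x0 = 401, s = 77.89, c = y2)),
              tau_breaks = c(5220, 7880), t0 = 18000)
grid <- seq(8000, 16600)
proxy <- data.frame(cal_bp = grid,
                    density = model_curve(truth$phases, truth$params,
                                          18000 - grid, truth$tau_breaks))

fits <- fit_growth_models(proxy, thin = 5)
fits$best
#> [1] "F"
best <- fits$fits[[fits$best]]
round(best$breakpoints_cal_bp)
#> [1] 12782 10124
attr(growth_rate(best), "phase_rates")[, c("form", "mean_rate", "min_rate", "max_rate")]
#>             form   mean_rate     min_rate max_rate
#>      exponential  0.04110000 4.110000e-02 0.041100
#>   decay_to_limit -0.02659488 -7.837917e-01 0.000000
#>         logistic  0.03245490 1.769696e-10 0.220498
```

The recovered phase structure reads directly in demographic terms: a
phase-1 exponential at 0.0411 %/yr (populations double about every
`round(doubling_time(0.0411))` = 1687 years; a 0.01958 %/yr whole-range
rate sustained over 10,000 years gives `fold_change(0.01958, 1e4)` ≈ 7.08,
a roughly seven-fold increase), a collapse phase whose rate starts near
−0.78 %/yr and decays to stationarity, and a logistic recovery whose
annual rate peaks near 0.22 %/yr before the population stabilises.

A full synthetic study — simulate a database, filter, bin, calibrate, build
the corrected SPD, bootstrap it, test it against the exponential null, fit
the models and correlate with a co-simulated proxy — is one call:

```r
cfg <- pipeline_config(scenario = list(preset = "model_f_study", n_dates = 600),
                       bootstrap = list(n_iter = 200), null = list(n_sim = 200),
                       models = list(thin = 5),
                       paths = list(output_dir = "out"), seed = 1)
run_pipeline(cfg)   # writes CSV/JSON artifacts + per-stage manifests to out/
```

## Scope

Calibration curves are consumed in the standard `.14c` dialect (synthetic
stand-ins are generated by `make_synthetic_curve()`; real IntCal/Marine
files work unchanged).  Environmental proxies are consumed as plain
`(cal_bp, value)` CSVs.  No GIS, no Bayesian sequence modelling, no
environmentally forced growth models.  See
`vignettes/paleodem-methods.Rmd` for the methods, assumptions, numerical
choices and known limitations.
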