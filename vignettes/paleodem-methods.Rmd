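---
title: "Inferring demographic change from radiocarbon records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring demographic change from radiocarbon records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodem)
```

## The population proxy

Under the "dates as data" assumption — that the amount of anthropogenic
carbon deposited, preserved and eventually radiocarbon-dated is proportional
to the number of people living at the time — the summed probability
distribution (SPD) of a region's calibrated radiocarbon dates is a proxy for
relative population size through time.  `paleodem` implements the full chain
from a raw date table to tested demographic growth models:

1. **quality control and binning** of the date database,
2. **calibration** of each determination against a calibration curve,
3. **SPD construction** with taphonomic correction,
4. **bootstrap** uncertainty quantification,
5. **significance testing** against a simulated exponential null,
6. **piecewise growth-model selection** with breakpoint scanning, and
7. **correlation** of the proxy with palaeoenvironmental series.

Every stage is testable offline because the package ships a synthetic-data
generator with known demographic ground truth.

## Calibration model

A calibration curve supplies, for every calendar year $t$ (cal BP), the
expected conventional radiocarbon age $\mu_c(t)$ and its uncertainty
$\sigma_c(t)$.  A measurement $x \pm \sigma_{lab}$ is calibrated by
evaluating, on a one-year calendar grid,

$$m(t) \propto \phi\!\left(\frac{x - \mu_c(t)}
{\sqrt{\sigma_{lab}^2 + \sigma_c(t)^2}}\right),$$

normalised to unit mass, where $\phi$ is the standard Gaussian density.
Normalisation makes every date carry equal weight in an SPD, which the
bootstrap below requires.  Marine-influenced samples are calibrated on a
mixed curve: $\mu_{mix} = (1-f)\mu_{atm} + f(\mu_{mar} + \Delta R)$ with the
variance combined in quadrature, where the marine diet fraction $f$ comes
from linear interpolation of $\delta^{13}$C between a terrestrial endpoint
(default $-21$ ‰) and a marine endpoint (default $-12$ ‰).  These endpoints
follow common marine-diet interpolation practice and are configurable; so is
the per-region reservoir offset $\Delta R \pm \sigma_{\Delta R}$.

Numerical choices: the calendar grid is fixed at one year because the
breakpoint scan downstream works in one-year increments; a calibrated
density's stored support is truncated where mass falls below $10^{-12}$ of
the peak, which bounds memory without affecting any tolerance used in the
package; and curves are re-ordered to an ascending calendar grid on input,
so all operations are invariant to the file's storage order.

## Database preparation

Three quality filters mirror standard practice for late-glacial date
compilations: laboratory errors must be strictly below 200 years; material
classes known to be unreliable (bulk sediments, land-snail carbonates, and
similar, coded `excluded_class`) are dropped; and multi-sample aggregates
are kept only when flagged stratigraphically consistent — that judgement
requires regional chrono-cultural knowledge, so it is an input column, not
something the package infers.  Every rejection is logged with a closed
vocabulary of reason codes so provenance can be audited mechanically.

To stop intensively dated occupation events from dominating the SPD, dates
are grouped per site into 200-year bins *before* calibration, by
single-linkage clustering on the uncalibrated age axis (a gap of exactly the
bin width keeps linking; a fixed-window alternative is provided since the
convention is not uniquely determined).  Within a bin, calibrated densities
are averaged, so each bin — not each date — contributes unit mass.
Replicate determinations of one event (equal `context_id`) are first pooled
by the Ward–Wilson inverse-variance mean when they pass the $\chi^2$
equivalence test at $\alpha = 0.05$; groups that fail, and groups mixing
calibration-curve classes, stay separate with a logged warning.

## SPD construction and corrections

SPDs are built separately for open-air sites, caves/rockshelters, and sites
of unknown type.  Open-air deposits are progressively lost to erosion and
burial, so the open-air component is divided by the taphonomic survival
function $s(t) = a\,(t + b)^{c}$ (defaults $a = 5.726442\times 10^6$,
$b = 2176.4$, $c = -1.3925309$, the global fit from the taphonomy
literature; all configurable) and rescaled to its original mass.  The
composite proxy is the pointwise sum of the three components.  An optional
non-linear scaling correction `density^(1/beta)` for the relationship
between energy consumption and population size ships disabled: it is not
part of the default modelling pipeline.

Edge effects are handled structurally: SPDs are built on a window broader
than the one analysed (defaults 18–7.5 kya build, 16.6–8 kya analysis), and
`trim_window()` enforces — rather than advises — that the analysis window
lies strictly inside the build window.

## Bootstrap and the exponential null

Calibration wiggles and laboratory error inject spurious peaks into an SPD.
To separate them from signal, the SPD is bootstrapped: each iteration draws
`n_bins` calendar ages from the observed SPD, back-calibrates each through
the curve (adding Gaussian curve noise $\sigma_c$), attaches a laboratory
error resampled from the empirical error pool, recalibrates, and sums.  The
pointwise median of the ensemble is the population proxy used for model
fitting, and the pointwise 2.3–97.7 percentile band is the 95.4% envelope
(percentiles rather than a Gaussian band, because calibration skews the
member distribution; the choice is switchable).  Errors are resampled with
replacement since the number of simulated dates can exceed the pool.

Long-term background growth is modelled by the exponential null
$y(t) = s\,e^{r (t_0 - t)}$, least-squares fitted with the amplitude
profiled out, leaving a one-dimensional optimisation over $r$.  The null
ensemble is built exactly like the bootstrap but with ages drawn from the
fitted null curve.  Departures are maximal runs where the observed proxy
leaves the envelope; the global statistic is the total out-of-envelope area,
and its significance is the rank-based Monte-Carlo p-value
$p = (1 + \#\{\text{sim} \ge \text{obs}\})/(1 + n_{sim})$, computed on the
raw density scale (the transform is configurable).  A regional record is
tested against the panregional trend by subsampling, without replacement,
the panregional bin pool at the region's bin count.

## The six growth models

Six candidate demographies are fitted to the proxy over the analysis window
and ranked by information criteria:

| model | phases | breakpoints |
|---|---|---|
| A | exponential | 0 |
| B | logistic | 0 |
| C | exponential / exponential | 1 |
| D | exponential / logistic | 1 |
| E | exponential / decay-to-limit / exponential | 2 |
| F | exponential / decay-to-limit / logistic | 2 |

All model arithmetic runs in forward time $\tau$ = years since the old edge
of the fitted window, and each phase is parameterised in its own local time.
The printed parameterisations of this model family in the literature are
ambiguous about the direction and origin of the time axis, so the package
fixes its own convention and reports growth rates — which are
convention-free — as the primary output.  Phase forms are
$\alpha e^{r\tau}$ (exponential), $a e^{-b\tau} + c$ (decay towards a
limiting population), and $A/(1 + e^{(x_0 - \tau)/s}) + c$ (logistic
density-dependent growth).

Phases are fitted independently on their sub-windows with no continuity
constraint, matching how per-phase parameters are conventionally reported.
Each phase fit uses variable projection: the linear parameters (amplitude
and offset) are profiled out in closed form, leaving a one- or
two-dimensional search — `optimize()` over the rate (exponential) or decay
constant, and Nelder–Mead with multiple starts over the logistic midpoint
and width.  This makes every fit deterministic and fast enough to sit
inside a breakpoint scan.  Two robustness constraints apply to the
logistic: the midpoint must lie inside its phase, and the transition width
$s$ must be at least 25 years (about one human generation) — on noisy
proxies an unconstrained logistic will happily model a single calibration
step as a demographic transition, which is exactly the artefact the
2000-year minimum phase duration is meant to exclude.

Breakpoints are anchored at climatic transitions (defaults 12.9 kya, the
Younger Dryas onset, and 10.2 kya, the Early Mesolithic onset) and scanned
in one-year increments within ±150 years.  The default scan is
coarse-to-fine (steps 30, 5, 1 year, each refining around the previous
optimum) because the total-RSS objective is locally smooth in the
breakpoints and the refinement reproduces the exhaustive optimum on clean
fixtures at a fraction of the cost; `scan = "exhaustive"` evaluates the full
grid (301 values per breakpoint, $301^2$ combinations for three-phase
models).  Every phase must last at least 2000 years; infeasible combinations
are skipped.

Ranking uses the Gaussian-RSS criteria $\mathrm{AIC} = n\ln(\mathrm{RSS}/n)
+ 2k$ and $\mathrm{SBC} = n\ln(\mathrm{RSS}/n) + k\ln n$, where $k$ counts
every free parameter *including each scanned breakpoint*.  An exactly zero
RSS is a perfect-fit sentinel ranked first.  Ties break by model id so
orderings are stable.

**Identifiability of breakpoints.** Because phases are fitted independently
and the phase forms are flexible, the RSS surface is nearly flat in the
breakpoints: a small boundary shift is absorbed by the adjacent phases'
parameters.  On noiseless proxies the scan recovers generating breakpoints
to within the scan step, but under realistic calibration noise individual
estimates wander tens to ~150 years and hit the scan bounds.  The package
therefore treats the scan range itself as the uncertainty statement
(`growth_rate_ci()` re-derives rates across breakpoint displacements and
bootstrap members), and users should read recovered breakpoints as anchored
climatic hypotheses, not free estimates.

Annual growth rates use the discrete definition
$100\,(y(\tau+1)/y(\tau) - 1)$ %, which equals $100(e^{r}-1)$ for an
exponential phase; rates are undefined across a breakpoint discontinuity
and reported per phase.  Two closed-form summaries are exposed:
`doubling_time(r) = ln 2 / ln(1 + r/100)` and
`fold_change(r, span) = (1 + r/100)^{span}`.

## Proxy correlation

Environmental series (ice-core $\delta^{18}$O, sea-surface temperature,
pollen percentages) are consumed as plain `(cal_bp, value)` tables — no
age-model work is attempted.  Series are aligned onto the SPD grid by
linear interpolation, or by block means when the proxy is denser than the
grid.  Spearman's rank correlation is computed against *every* bootstrap
member, so the spread of coefficients expresses dating and calibration
uncertainty; the reported value is the ensemble mean ± standard deviation
(the "±" is interpreted as ensemble SD), with a p-value from the
member-median coefficient.  Environmental instability per demographic phase
is the variance of the residuals after removing an OLS linear trend, using
the best-fit breakpoints so the two modules stay consistent by
construction.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a real compilation: calendar
ages drawn in proportion to a known demographic curve (thinned by the
survival function for open-air sites when taphonomic loss is enabled),
back-calibrated through a synthetic curve with curve noise, given truncated
log-normal laboratory errors (capped below 200 yr so fixtures pass the
error filter unless a violation is injected), and wrapped in
site/region/material/context metadata.  Defaults are chosen to match the
scale of late-glacial Iberian-style compilations: ~100 sites with about
five dated occupation episodes each (dates are assigned to sites in
temporally contiguous episode blocks, which is what makes per-site binning
meaningful), curve uncertainty of 30 ¹⁴C yr and lab errors centred near
60 yr.  The default test curve is "wiggly"
($\mu_c(t) = t + A\sin(2\pi t/P)$, monotonicity checked) because it
exercises multimodal calibration without external curve files.

The `model_f_study` preset encodes a three-phase trajectory of the
magnitudes reported for the Iberian Late Glacial: exponential growth at
0.0411 %/yr to a breakpoint at 12,780 cal BP, a decay-to-limit phase whose
initial rate is −0.79 %/yr, and a logistic recovery (width 77.89 yr,
midpoint ~400 yr into the phase) whose annual rate peaks near 0.22 %/yr.
The one quantity the source material does not pin down — the phase-2
limiting level — is set once to half the pre-decline level.

What the generator does *not* emulate: real IntCal-style curve structure
(plateaus and reversals beyond a single sinusoid), regionally varying
reservoir offsets, research-history biases in site discovery, or the actual
geography of any study area.  Tests passing on synthetic data therefore
validate the estimators and the pipeline plumbing, not any empirical claim
about a real record.

Proxy co-simulation uses a Gaussian copula: the reference curve's normal
scores are mixed with independent noise at the Pearson weight
$2\sin(\pi\rho_s/6)$ that yields a target Spearman correlation $\rho_s$.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen so
each statistical property is measurable with comfortable margins: 500-date
scenarios for rate recovery, 50 replicates for model identification, 500
replicates with 200 null simulations each (40 dates per replicate on a
short identity-curve window) for the type-I-error calibration of the global
test, and 500 vs 1000 iterations for bootstrap stability.  All stochastic
operations take explicit seeds and are bit-reproducible given
(seed, iteration count); the pipeline derives one deterministic sub-stream
per stage from a single global seed.

## Known limitations

* Calibration smoothing attenuates sub-century rate extremes: fast
  transitions (the initial collapse rate, the logistic peak) are recovered
  closer to zero than their generating values at realistic dating errors.
  The package reports what the proxy supports; it does not deconvolve.
* Breakpoint point-estimates are weakly identified (see above).
* The taphonomic correction interacts with binning: where several dates of
  one site fall into one bin, part of the thinning signal is absorbed by
  binning before the correction sees it.
* No Bayesian sequence/phase modelling is attempted; pooling is limited to
  R_Combine-equivalent Ward–Wilson means.
* Uniform and logistic nulls are deliberately absent from the significance
  test; logistic dynamics enter as fitted models, not as nulls.
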