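---
title: "Methods: temporal scales of adult mosquito abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal scales of adult mosquito abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Daily light-trap records of adult mosquitoes fluctuate over every time
scale from two days to several years, and the number of trapped
individuals is not the population: it is the *active* (host-seeking)
fraction of it, which responds to weather within a day. `mosquitodyn`
provides the analysis chain needed to take that seriously: spectral and
autocorrelation descriptions of daily abundance series, a mechanistic
life-cycle simulator whose output can be "observed" through a
rainfall-driven activity filter, and canonical density-dependent models
as a baseline that lacks the activity mechanism.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical and design choices, in the package's own
words.

## Spectral description

`power_spectrum()` evaluates the discrete Fourier transform of a
uniformly sampled series of length $N$ and sampling interval
$\Delta t$ on the period grid $T_i = N\Delta t/i$, $i = 1..N/2$, and
reports $S(T_i)$, the squared amplitude of the sinusoidal component of
period $T_i$. The normalisation is fixed by the convention that a pure
sinusoid of amplitude $A$ confined to one bin has peak power exactly
$A^2$: $S_i = (2/N)^2 |X_i|^2$ with $X$ the raw DFT. Under this
convention the biased sample variance equals $\sum_i w_i S_i$ with
$w_i = 1/2$ (and $1/4$ at the Nyquist bin for even $N$);
`spectrum_variance()` performs that Parseval check, and the test suite
verifies the whole spectrum against a direct $O(N^2)$ projection.

Choices worth stating:

* **Detrending.** Whether the source record was mean-removed or
  transformed before its published spectra is not stated anywhere we
  could rely on; `detrend = "mean"` is the default (the $i=0$ bin is
  excluded from peak search either way) and a `log1p` option exists and
  is flagged in the output.
* **No tapering by default.** A Hann window is available
  (`taper = "hann"`) but plain DFT is the default, matching standard
  practice for peak *location* (rather than leakage-sensitive
  amplitude) questions.
* **Peak detection** (`find_peaks()`) smooths the periodogram with a
  3-bin moving average before the local-maximum scan, because raw
  periodograms of noisy ecological series are jagged; the width is an
  argument, ties break toward the longer period, and the resolvable
  band is $[2\Delta t, N\Delta t]$ — `nyquist_period()` makes the lower
  limit explicit (14 days for weekly trapping).

## Correlograms and the weekly degradation experiment

`acf_fn()` uses the biased ($1/n$) autocorrelation estimator, which is
positive semidefinite — a requirement of the Durbin–Levinson recursion
by which `pacf_fn()` obtains partial autocorrelations. The 95% band is
the white-noise large-sample approximation $\pm 1.96/\sqrt{n}$.
`weekly_subsample()` splits a daily record into the 7 series a
once-a-week trapping programme would have produced, one per weekday,
each with $\Delta t = 7$ d. `significant_positive_run()` operationalises
statements like "significantly positive out to about 11 weeks": the
largest lag $L$ with all of lags $1..L$ above the $+$band, reported in
days so daily and weekly designs are comparable.

Winter zeros are retained in correlograms (no documented exclusion rule
exists for the source records); masking them is possible upstream but
is not done by default.

## The individual-based life-cycle simulator

Three stages are modelled — egg, larva/pupa, adult — as *cohorts*:
individuals created the same day, in the same stage, with the same
sampled residence time. Cohorts are thinned binomially each day, which
is statistically identical to per-individual simulation. All
environmental drivers enter through 10-day **trailing** moving averages
(`moving_average()`): development and survival on day $t$ must not
depend on future weather, and partial windows at the series start let a
run begin on day 1.

Daily order of operations in `step_day()`:

1. **Survival thinning.** Base daily survival is a quadratic in the
   10-day mean temperature (or a constant), multiplied by a dry-spell
   penalty when the 10-day mean precipitation is below 1 mm/day
   (larvae and adults), and by the linear density-dependence factor
   $\max(0, 1 - s\,n_{stage})$ (eggs and larvae), clipped to $[0,1]$.
2. **Development clocks.** Residence times are sampled at cohort
   creation from $\mathrm{Normal}(A\,T^{-a}, 1\,\mathrm{d})$, rounded
   to whole days and floored at 1; temperature is clamped at 1&nbsp;°C
   before the power law, which diverges at 0. The clock itself is kept
   as the *fraction* of development remaining and advances by
   $1/d_{mean}(T_{today})$ per day (rate summation). At constant
   temperature this reproduces the sampled duration exactly; under
   seasonal forcing it is what keeps slow developers viable — a
   winter-created larva of a slow species would otherwise carry a
   clock of hundreds of days that ignores the coming summer.
   Clocks of the overwintering stage (eggs for *Ae. vexans*, larvae
   for *Cs. melanura*) freeze below the diapause temperature.
3. **Transitions.** Eggs hatch to larvae; for the floodwater
   *Ae. vexans* hatching additionally requires an inundating rain
   (≥ 5 mm/day), a warm-enough 10-day mean (≥ 15 °C), and releases
   only half of the ready egg bank per event (installment hatching).
   These last two are floodwater egg-bank biology: without them the
   over-wintered bank is dumped into lethal early-spring conditions
   and simulated populations go extinct within a few years. Larvae
   emerge as adults and draw their first gonotrophic clock.
4. **Reproduction.** Adults completing a gonotrophic cycle succeed in
   a blood meal with a Bernoulli probability (linear in 10-day mean
   relative humidity for *Ae. vexans*; increasing quadratic in 10-day
   mean temperature for *Cs. melanura*), lay a batch of
   $\mathrm{Normal}$ size whose mean increases with the day's
   precipitation, and start another cycle until they die. Only females
   are modelled; offspring counts are halved at creation
   (`female_fraction = 0.5`).

Gonotrophic cycles: truncated normal (mean 10 d, sd 1 d, bounds
7–13 d) for *Ae. vexans*; normal with a temperature-decreasing mean,
unit sd and a 1-day floor for *Cs. melanura* (whether those draws are
truncated is not documented; the floor is the package's choice).

### Species parameters

Every biological coefficient lives in a YAML file
(`inst/extdata/species/`), one per species, loaded by
`species_params()`. The development exponents ($a$ = 1.90 and 1.86 for
*Ae. vexans* embryogenesis and larval stage; 0.30 and 2.25 for
*Cs. melanura*) are literature values; the printed 0.30 for
*Cs. melanura* embryogenesis is anomalously small next to the others
and may be a truncated 2.30 — both readings are one line apart in the
YAML and neither is silently preferred. The $A$ coefficients, survival
quadratics (optimum, peak, half-width), density-dependence slopes,
blood-meal and egg-batch coefficients are **not** published at this
level of detail and are package defaults, chosen once as follows and
then frozen:

* *Ae. vexans*: embryogenesis ≈ 3 d and larva→adult ≈ 8 d at 25 °C
  (a full generation under 3 weeks in favourable conditions); larval
  survival peaking 0.97 near 26 °C (half-width 35 °C), adult 0.92 near
  24 °C (width 28 °C); durable diapausing eggs (0.998/day).
* *Cs. melanura*: exceptionally slow larval development
  (≈ 135 d at 18 °C, ≈ 64 d at 25 °C — immatures spend months in
  crypts), cold-tolerant long-lived adults (survival 0.97 near 20 °C,
  width 30 °C), larval survival 1 under zero crowding and wet
  conditions. With these values the endogenous configuration (constant
  18 °C, rainfall effects off) oscillates around its carrying capacity
  with a dominant spectral period near 180 days, the documented
  signature of the endogenous dynamics; the package's acceptance
  script recomputes that period from scratch.
* The dry-spell penalty is 0.97/day (*Ae.*) and 0.99/day (*Cs.*,
  buffered crypt habitat). A much harsher penalty compounds over
  week-to-month stage durations into guaranteed extinction under any
  realistic rainfall intermittency, so these values are set by the
  viability of the simulated populations, not by fitting to any
  record.

`run_ibs()` runs `n_reps` replicates (default 20), seeding replicate
$r$ with `seed + r`; three forcing configurations are supported:
`full_weather`, `temperature_only` (rainfall effects off), and
`endogenous` (constant temperature, default 18 °C, rainfall effects
off). The default initial condition is 500 individuals in the species'
overwintering stage, and the first 365 days are discarded by the
analysis helpers.

### The activity (observation) layer

`apply_activity()` converts "actual" adults into "observed" counts:
each day a fraction $a(p_t)$ of adults is trappable, applied as a
binomial draw (or deterministically). `parametric_activity()` is a
piecewise log-linear hump — rising below an optimum rainfall intensity
(default 2 mm/day), falling steeply above it, bounded in
$[\mathrm{floor}, 1]$. The empirical counterpart is
`activity_ratio_series()` (the day's count over the maximum count in a
moving 31-day window — the window maximum proxies the trappable
population under the most favourable conditions of a homogeneous
period) binned by rainfall intensity in `bin_by_rainfall()`. The
31-day window is **centered** by default (symmetric reading of a
"moving window"; a trailing option exists), windows with a zero
maximum give undefined ratios that are excluded from binning (winter
zeros would otherwise contaminate the curve), and the default bin
edges 0, 0.5, 1, 2, 5, 10, 20, ∞ mm/day are a package choice, exposed
as an argument.

## Density-dependent population models

`fit_density_model()` calibrates, by ordinary least squares on
$\log(N_{t+1}/N_t) = a + b\,D_{t-\ell} + \sum_j c_j E_{j,t}$,
the Ricker model ($D = N$, $r_m = a$, $K = -a/b$) and the
Gompertz-logistic model ($D = \log N$, $\log K = -a/b$), with density
lags $\ell = 0..5$ and optional additive environmental covariates.
Transitions touching zero abundance are dropped (the linearisation
needs a log of a ratio) and their count is always reported — an offset
such as $+1$ would silently distort the fitted curvature.
`multi_lag_fit()` adds one density term per lag and reports
standardised coefficients; `simulate_density_model()` iterates a fitted
recursion with Gaussian log-scale noise of the fitted residual sd.
No bias correction is applied to the least-squares estimates: the
package compares correlation *structures* of simulated and observed
series, not parameter truth.

## Synthetic data

`generate_weather()` produces an annual temperature sinusoid (coldest
around Jan 15) with AR(1) noise, wet/dry Bernoulli rainfall with
exponential wet-day depths, and humidity elevated on wet days.
`generate_abundance()` produces trap-like daily counts: baseline plus
sinusoidal components, floored at zero, zeroed in a winter window, with
negative-binomial noise (default size 0.8) — Poisson noise cannot
produce the order-of-magnitude day-to-day swings daily trap records
show. `generate_density_series()` iterates the Ricker/Gompertz maps
exactly (`noise_sd = 0`) or with multiplicative log-normal noise.

What the generators deliberately do **not** emulate: storm clustering
(rain days are independent, so the activity-induced observational
memory is a little shorter than under real, persistent rainfall),
regional climatology of any particular station, multi-year abundance
trends, and trap-specific detection artefacts. Passing tests therefore
demonstrate that the machinery recovers known structure planted under
these idealised conditions — not that any particular field record will
show the same numbers.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds (`withr::with_seed`); no
  function leaves the global RNG state altered.
* Sampled whole-day durations are drawn by discretising the normal
  onto days ($P(\mathrm{round}(X) = k)$, edge bins absorbing the
  tails) and splitting cohorts multinomially — exactly the
  distribution of rounded per-individual draws at a fraction of the
  cost.
* Development clocks treat a residual below $10^{-9}$ as complete, so
  floating-point residue cannot delay a transition by a day.
* Gaps: abundance gaps are never interpolated silently
  (`read_abundance()` flags them; `fill_gaps()` bridges runs up to
  `max_gap` only, and refuses longer ones because interpolation
  injects spurious low-frequency power); weather gaps up to 7 days are
  interpolated with a logged gap report.
* Empty populations are absorbing; zero-length bands, misaligned
  series, non-daily inputs and invalid parameters raise errors naming
  the violated constraint.

## Problem sizes

The test suite uses series of $10^2$–$4\times10^3$ points, $10^5$-draw
Monte-Carlo checks, and simulator runs of 2–5 years with 1–5
replicates; the acceptance script runs the full 20-replicate, 9-year
endogenous configuration. The whole suite completes in about a minute
on one core.

## Known limitations

* No spatial structure or hydrology: water availability enters only
  through precipitation rules.
* The IBS is deliberately uncalibrated; its coefficients are
  literature-shaped stand-ins and all claims made of it are
  structural (periodicities, correlation signatures), not numerical
  abundance predictions.
* PACF confidence bands use the white-noise approximation at every
  lag.
* The weekly degradation experiment assumes a strictly daily input
  calendar.
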