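---
title: "Methods: the trapshy population model, its calibration, and the lure scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the trapshy population model, its calibration, and the lure scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapshy)
```

`trapshy` simulates an invasive predator population (parameterised for New
Zealand brushtail possums) under a kill-trapping operation, infers the
population's distribution of trap-shyness from a capture time series, and
compares multi-lure control strategies. This vignette is the package's own
account of the model, the choices made where the design was genuinely open,
and what the tests do and do not demonstrate.

## The individual-based model

Every individual carries a fixed home-range centre, an age (juveniles
mature at 365 days), and one interaction probability `p_int` per lure,
drawn at initialisation from a Beta distribution parameterised by its mean
`mu0` and variance `s0^2` (`beta_params_from_moments()`). Heterogeneity in
`p_int` *is* trap-shyness in this model: a U-shaped Beta (both shapes
below 1) describes a population split into very shy and very trappable
animals.

Each simulated night, in order:

1. **Adult census.** On 1 February (the reproduction-season onset) the
   adult count `N*` entering the density-dependent birth rate is
   re-recorded. Before the first onset in a run, `N*` is the initial adult
   count.
2. **Births.** `Binomial(adults, B(t) * dt)` with
   `B(t) = max(0, alpha - c N*) f(t)`. The seasonal density `f` is a
   normal over the calendar year (peak day 91, sd 20 d) truncated to
   [0, 365] and renormalised, so it integrates to one and converts the
   annual rate to d^-1 on its own; the constant mortality below is instead
   divided by 365. `c = (alpha - M)/(A K)` makes `alpha - c N* = M` hold
   exactly at `N* = A K`, pinning the no-trapping equilibrium at carrying
   capacity. Newborns get uniform centres and fresh Beta `p_int` draws;
   they can die and be trapped like adults but do not enter `N*` until one
   year old.
3. **Natural deaths.** Per-individual Bernoulli at `M/365 * dt`,
   `M = 1/lifespan`.
4. **Captures.** Population density `D = N_alive / A` sets the half-normal
   home-range scale `sigma = min(73.7 D^-0.4, 155)` m and the centre
   capture probability `g0 = min(1, 5.67 sigma^-0.99)`; all individuals
   share the population-level `sigma` and `g0` (heterogeneity enters only
   through `p_int`). The nightly chance of encountering a trap at distance
   `d` is `p_enc(d) = min(1, (g0/mu0) exp(-d^2 / 2 sigma^2))`, combined
   across the active traps within `2.45 sigma + 10` m of the centre as
   `p_encTOT = 1 - prod(1 - p_enc(d_j))`. On an encounter, a lure is
   sampled from the night's lure mix, and a Bernoulli trial with that
   lure's `p_int` decides capture; captured animals are removed.

### Numerical and structural choices

Where the model description leaves room, the package resolves it as
follows, once:

- `g0/mu0` can exceed 1 (small `mu0`), and the raw `g0` law exceeds 1 for
  `sigma` below about 5.8 m; both are clamped because they are
  probabilities. Negative birth rates at very high density clamp to 0.
- Event order within a day is births, then natural deaths, then captures;
  order effects are second-order in `dt` (1 day).
- Home-range centres are continuous-uniform over the study rectangle, not
  a lattice.
- The trap perception distance (10 m, an assumed constant) only pads the
  trap-inclusion radius; setting it to 0 recovers the strict `2.45 sigma`
  home-range circle.
- Traps have no saturation or reset downtime: the capture model has no
  occupancy term, and field re-setting is absorbed into `g0`.
- Births use the *adult* count while deaths apply to everyone. A
  consequence worth stating: the equilibrium condition `alpha - c N* = M`
  constrains the adult population, so the long-run adult average sits at
  `A K` (1575 for the default 175 ha at 9 ha^-1) while the total
  population additionally carries a standing juvenile cohort of roughly
  7%. The equilibrium acceptance test therefore measures adults, the
  quantity the condition actually constrains.
- The study area constant `A = 175` ha is the density normaliser; the
  1160 x 1660 m rectangle (which encloses the trap layout with a 100 m
  buffer, and is not exactly 175 ha) is purely the geometric extent for
  home-range centres.
- The catch-rate trigger compares the 7-night trailing mean against the
  first-7-nights baseline with a 1e-12 tolerance so exact-threshold ratios
  are not lost to floating-point rounding; it fires at most once, from
  night 8, and immediately at night 8 if the baseline is zero.

### Engines

The daily loop is implemented twice: a compiled Rcpp engine (the default;
it caches each individual's distance-sorted trap neighbourhood and
refreshes encounter probabilities only when the population composition or
the active-trap set changes) and a readable pure-R reference
(`step_day()`, `nightly_captures()`). Both draw from R's RNG, so each is
reproducible from `set.seed()`, but they consume the stream in different
orders; the test suite checks them against each other statistically and
checks the conservation identity `N0 + births = alive + deaths + captures`
on both.

## ABC calibration

`trapshy()` fits `(mu0, s0^2, N0)` by rejection ABC: uniform priors
(`mu0 ~ U(0.1, 0.9)`, `s0^2 ~ U(0.01, 0.2)`, `N0 ~ U{140..280}`, the
population prior being left-bounded by the observed capture total and
right-bounded by double it), one forward simulation per draw, mean squared
error of *cumulative* captures at the check dates, and retention of the
smallest-error 1%. Choices made here:

- The discrepancy uses cumulative counts at the observation timestamps:
  they are monotone, robust to irregular check intervals, and match how
  such series are reported. Per-interval counts can be formed from the
  optional `nightly_captures` CSV column if wanted.
- One stochastic replicate per prior draw — standard rejection ABC; with
  30,000 draws the design totals 30,000 model runs.
- Prior draws violating Beta-moment validity (`s0^2 >= mu0(1 - mu0)`) are
  resampled jointly. This truncates the joint prior and slightly reweights
  the marginals towards central `mu0`; the test suite pins the resulting
  marginal means against an independent rejection-sampling oracle.
- Rejection keeps exactly `ceiling(fraction * n)` draws; ties break by
  draw order. Credible intervals are equal-tailed 2.5%/97.5% quantiles
  with linear interpolation (R's default type 7); accepted samples are
  *not* weighted by goodness of fit when summarised — pure rejection ABC.

## Lure scenarios

`build_scenarios()` defines seven deployments: the single-lure baseline;
lure B (same Beta mean and variance as A) or lure C (double the mean, same
variance) deployed simultaneously with A, with a 50/50 chance of either
lure on each encounter; or switched in permanently once the trailing catch
rate has dropped by `rc` = 80% or 90%. Per-lure `p_int` values are drawn
independently per individual — the best-case assumption that a shy animal
towards one lure may love another; `run_scenarios(correlated_lures = TRUE)`
provides the opposite degenerate mode (identical draws), under which a
two-lure deployment provably collapses onto the baseline and is tested to.

- Doubling the mean can leave (0, 1): the secondary mean is capped at
  0.95, and if the inherited variance then violates Beta validity it is
  shrunk to 0.9 times the validity bound — both caps preserve the "more
  attractive" ordering.
- Scenario replicates draw accepted posterior triples uniformly with
  replacement. `N0` is used unscaled on the generic 100 ha, 100-m-grid
  scenario landscape even though fitting used 175 ha, mirroring the
  calibration-then-scenario procedure; rescaling by density is a
  one-line change via the `params` argument if preferred.
- Every scenario is run from the same seed, so replicate `r` of each
  scenario sees the same posterior draw — a paired design that sharpens
  the between-scenario survivor contrasts.
- "Plateau" is not a standard quantity; `plateau_day()` defines it as the
  first night after which the 7-night trailing mean stays below 5%
  (configurable) of the initial rate for the rest of the run.
- The switch thresholds default to {0.8, 0.9}.

## The synthetic-data generator

`generate_study()` provides ground-truth datasets so the calibration and
the scenarios are testable without any field download. It emulates the
*structure* of the motivating field study: 66 traps active from early May
growing to 105 by mid July along synthetic transect polylines (straight
lines with 100-150 m jittered spacing — the real layout's statistics, not
its geometry), the 1160 x 1660 m extent, twice-weekly checks for eight
weeks whose interval then grows by 1.5x per month up to 28 days (the
lengthening rule is invented; only "twice weekly, then progressively
longer" is given), and an 8-month window from 1 June. The default ground
truth `(mu0 = 0.3, s0^2 = 0.1, N0 = 200)` sits inside the priors so
recovery experiments are well-posed, and produces on the order of 140-170
captures, the magnitude of the motivating dataset. An optional Gaussian
observation-noise knob (`obs_noise_sd`, default 0 — kill-trap counts are
exact) perturbs the cumulative series (monotonicity restored by a running
maximum) and exists to study how posterior precision degrades with noisier
data.

What the generator does *not* emulate: the real transect geometry,
immigration or range expansion, a second spring breeding season, learned
shyness after failed interactions, trap failures, or habitat covariates.
Passing the recovery tests therefore shows the inference machinery is
self-consistent under the model's own assumptions — not that those
assumptions hold in any particular forest.

## Problem sizes used by the tests and the acceptance script

The packaged checks run at sizes chosen to give stable statistics on a
single core: the encounter-probability Monte-Carlo oracle uses 1e5
replicates on 20 random trap sets; the demographic-equilibrium run covers
20 years from 1575 adults; the parameter-recovery experiment fits 20
replicate synthetic studies with 3000 draws at 1% acceptance and requires
the nominal 95% intervals to cover the true `mu0` and `N0` in at least 80%
of replicates; scenario comparisons use 250-500 paired replicates.
`scripts/acceptance.R` recomputes the headline quantities at 6000 draws
and 2000 scenario replicates. The full-scale design (30,000 draws, 10,000
replicates) is available by passing those values to `trapshy()` and
`run_scenarios()`.

## Known limitations

Closed population (no immigration — a recognised driver of long-term
eradication failure), a single annual breeding pulse, no learned
trap-shyness, no per-individual variation in `sigma` or `g0`, no explicit
trap occupancy, and lure attractiveness assumptions (independence;
doubling) that are modelling devices rather than measured quantities. The
50/50 per-encounter lure rule also presumes dense trapping; with sparse
grids or more than two lures, explicit lure placement would matter.
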