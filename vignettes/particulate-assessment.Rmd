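---
title: "Methods: satellite-driven particulate assessment with paqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite-driven particulate assessment with paqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`paqr` implements a complete particulate-pollution assessment chain:
estimation of PM10 and PM2.5 concentration grids from satellite and
reanalysis predictors with a Levenberg–Marquardt (L-M) back-propagation
network, individual air-quality indexes by breakpoint interpolation, a
composite particulate index with extreme-value weight modification, and
zonal population-exposure statistics. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where more than one defensible reading existed.

## 1. The estimation model

### Predictors and screening

Surface PM concentration correlates with column aerosol load (AOT) but the
relationship is confounded by aerosol type (SSA), hygroscopic growth (RH),
vertical dilution (HPBL), ventilation (WS), surface thermodynamics (SKT)
and broad geography (latitude, longitude). All eight enter as plain numeric
predictors, standardised to zero mean and unit variance by the training
split's statistics.

Before training, `stepwise_select()` screens candidates on an ordinary
linear model of the observed concentration: forward selection with
backward elimination, governed by partial-F p-values with entry threshold
`alpha_enter = 0.05` and removal threshold `alpha_remove = 0.10` (the
classical defaults; entry must be no laxer than removal or the procedure
can cycle). Screening on a linear surrogate is deliberately cheap — its
purpose is to spare the network from fitting irrelevant inputs, not to
capture the nonlinearity itself. Users screening many candidates should
tighten `alpha_enter`, since the false-entry rate per step is the alpha
level by construction.

### Network and optimiser

The estimator is a fully connected feed-forward network with one hidden
layer of tanh units and a linear output, default `layer_sizes = c(8, 16,
1)`. A single hidden layer is a universal approximator for continuous
functions on a compact domain, and L-M training — which builds the full
Jacobian and solves a dense normal system per step — scales poorly with
parameter count, so depth buys little here; `layer_sizes` nevertheless
accepts arbitrary hidden depth, and `c(p, 1)` degenerates to a linear
model (useful as a least-squares oracle: with no hidden layer the trained
coefficients match OLS to numerical precision).

`lm_fit_network()` minimises the sum of squared errors with damped
Gauss–Newton steps `(JᵀJ + λI) δ = Jᵀr`. The damping schedule is the
classical Marquardt one: λ starts at 10⁻³, is divided by 10 after every
accepted step and multiplied by 10 after every rejected one, and the fit
aborts when λ exceeds 10¹⁰. Accepted steps never increase the training
SSE — the stored trajectory is non-increasing by construction, and the
test suite asserts it. Stopping criteria: `max_iter` accepted steps
(default 100), gradient max-norm or relative SSE decrease below `tol`
(default 10⁻⁸), or λ overflow.

With flexible networks and noisy targets, running L-M to convergence
interpolates the observation noise. The standard guard, implemented here,
is validation-based early stopping: each run holds out a validation split,
the validation SSE is tracked along the trajectory, the returned weights
are the iterate that minimised it, and optimisation stops after `patience
= 6` consecutive accepted steps without a validation improvement.

### Repeated random sampling

`train_lm()` repeats training over `n_runs` independent random
train/validation splits (default `split_fraction = 0.8` train) with
seeded small-uniform weight initialisation (U(−0.5, 0.5) on standardised
inputs), and returns the run with the highest validation Pearson r. The
default `n_runs = 50` is a desk-scale choice: on the synthetic fixtures
accuracy saturates well before 50 runs, and the parameter is exposed for
users who want more. All seeds derive from one master seed through the
splitting rule `sub_seed(seed, k) = (seed + 99991·k) mod (2³¹ − 1)`, so a
fixed seed reproduces every run bit for bit.

Validation quality is summarised by Pearson r and by APE, the mean of
per-record absolute percentage errors `100·|Y_est − Y_obs|/Y_obs` — a
per-record quantity, so zones of low observed concentration dominate it;
it is undefined (an error, never silently dropped) when an observed value
is not strictly positive.

## 2. Index construction

### Individual indexes

`iaqi()` maps concentration to index through an ordered breakpoint ladder
by linear interpolation within the containing segment, returning the cap
index (500) above the last breakpoint. The shipped ladders are the 24-hour
PM2.5 and PM10 tables of the Chinese AQI standard (HJ 633-2012). Two
conventions are explicit knobs rather than hard-coded behaviour:

* breakpoints are **data** (`breakpoint_table()`, JSON round-trip), since
  standards differ by jurisdiction and averaging period — applying annual
  means to 24-hour ladders, as large-scale mapping studies effectively do,
  is a configuration choice the user owns;
* the index is real-valued by default; the reporting convention of
  rounding up to the next integer is the opt-in flag `integer_ceiling`,
  because gridded maps and downstream weighting need the unrounded value.

### Composite index

For individual indexes `I` the raw weights are index shares,
`Q_i = I_i/ΣI_j`. We adopt this form because it is the simplest weighting
that is index-proportional and confined to [0, 1] with ΣQ = 1. With
unmodified weights the composite `ΣQ_iI_i = ΣI²/ΣI` is the
mean-square-over-mean, always at least the arithmetic mean — the composite
deliberately leans toward the worse pollutant.

Raw weights misbehave in extreme-dominance situations such as dust storms,
where the coarse-particle index is very large and the fine-particle index
small: the small index's near-zero weight still dilutes the composite.
`modify_weights()` counts extremes — `s` weights below `low_cut = 0.05`
and `t` above `high_cut = 0.5` — and, only when both kinds are present,
truncates the sub-`low_cut` weights to zero and renormalises. This rule
was chosen because it (a) reproduces the intended dust-storm behaviour
exactly (the composite equals the dominant index), (b) degenerates to the
raw weights when no extreme configuration exists, and (c) is idempotent.
Whether large weights should additionally be boosted beyond
renormalisation is genuinely open; we implement only the truncation and
report `t` for diagnostics. The cutoffs are arguments everywhere they
appear.

`classify()` buckets index values into the standard six categories with
half-open intervals (a value exactly on a bound belongs to the upper,
worse category — the conservative reading for a pollution scale);
moderate pollution begins at 150 and heavy at 200 under the default
scheme, and the bounds are configurable.

## 3. Exposure statistics

Per zone, over valid cells: `pw_pm25 = Σ PM_i·P_i / Σ P_i` is the
population-weighted mean concentration — the exposure of the average
resident, invariant to uniform population rescaling and always inside the
zone's concentration range. `pc_pm25 = Σ PM_i·P_i / n` is a
population–concentration product normalised by zone area (cell count); it
scales linearly with population, so small dense zones rank high even at
moderate concentrations. The product form is the default because it is
the reading under which the two statistics tell complementary stories
(the ratio in one, the mass in the other); the alternative simple-mean
reading `Σ PM_i / n` is available via `form = "simple_mean"` for
sensitivity analysis, and reports always carry the form used. Zones with
zero population report PW as `NA` — an undefined ratio, never fabricated
as 0. Population rasters are treated as persons per cell;
`density_to_count()` converts persons-per-km² products using the
spherical cell area at each latitude.

## 4. The synthetic study region

`sim_config()` drives a generator whose defaults define the package's
reference conditions: a 40×40 grid of 0.1° cells, 300 stations, 8 zones,
spatial correlation length 5 cells, observation noise 8 µg/m³.

* **Predictor fields** are Gaussian random fields (white noise smoothed by
  a truncated Gaussian kernel of width `smoothness`, then standardised),
  affinely mapped to realistic ranges and clipped to physical bounds
  (RH ∈ [0, 100] %, SSA ∈ (0, 1], AOT ≥ 0 and log-normal-skewed,
  HPBL > 0 m, WS ≥ 0 m/s).
* **Truth surfaces** follow the documented smooth function of
  [`truth_spec()`]: increasing in AOT and RH, decreasing in HPBL and WS,
  with a non-negative coarse-mode addition tied to low single-scattering
  albedo so PM10 ≥ PM2.5 everywhere. Coefficients were set once to give
  concentrations spanning roughly 15–300 µg/m³ with a spatial standard
  deviation near 50 µg/m³ — a heavily polluted continental region, which
  is the regime where a composite particulate index is interesting.
* **Stations** sample valid cells without replacement and observe
  truth + N(0, `noise_sd`); `noise_sd = 8` µg/m³ is a plausible scale for
  annual-mean ground records (instrument plus collocation error).
* **Population** is a lightly smoothed log-normal rural background with
  `n_zones` Gaussian urban clusters at well-separated centres; **zones**
  are a Voronoi partition around seeded centres — contiguous, exhaustive,
  province-like.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: satellite retrieval artifacts (cloud
gaps, aerosol-type misclassification), seasonal and diurnal cycles,
spatially correlated observation error, station siting bias toward
cities, and real geography. The generator establishes that the chain
recovers a known nonlinear truth under clean conditions; transfer to real
retrievals must be validated against real ground networks.

## 5. Numerical choices and degenerate inputs

* Grids are north-up matrices (row 1 northernmost), origin at the
  upper-left corner, positive x step and negative y step; no resampling
  is ever performed — `align_check()` rejects misaligned stacks naming
  the first mismatching pair, with transform tolerance 10⁻⁹.
* Missing data propagate conservatively: a cell masked in any input of a
  multi-field computation is masked in the output; masked cells never
  enter any statistic.
* Grid files are ESRI ASCII grids (a standard plain-text raster format)
  written at full double precision, so write/read round-trips are exact;
  a JSON sidecar carries the CRS label and units the format cannot.
  No-data sentinels are adjusted automatically on collision with valid
  values.
* Negative network predictions (possible under extrapolation) are floored
  at zero with the floored-cell count attached to the output.
* All-zero index vectors make the composite weighting undefined: an
  error, not a silent 0. Constant screening candidates are dropped with a
  warning; singular entries are skipped.
* Standardisation scales of constant columns are replaced by 1 to avoid
  division by zero (the column then contributes nothing).

## 6. Problem sizes in the shipped tests

The test suite exercises the chain at sizes chosen to make the scientific
checks sharp while keeping the suite quick to run as a development tool:
the truth-recovery experiment uses the full default fixture (40×40 grid,
300 stations, 16 hidden nodes, 50 runs); property sweeps use 8×8–30×30
grids and 50 seeds; the end-to-end determinism check uses a 24×24 grid
with 6 training runs, since bit-reproducibility is independent of problem
size. `scripts/acceptance.R` re-runs the full default chain from scratch
and writes its headline numbers as JSON.

## 7. Known limitations

* L-M training builds the dense Jacobian; it is the right tool up to a
  few hundred parameters and thousands of records, not for deep or wide
  networks (no GPU path, no stochastic optimisers).
* The exposure statistics are ecological: no demographic stratification,
  time-activity weighting, or concentration–response modelling.
* Gaseous pollutants (SO₂, NO₂, CO, O₃) and the full multi-pollutant AQI
  are out of scope; the composite index covers particulate fractions
  only.
* The toolkit assumes pre-aligned grids; reprojection and resampling
  belong upstream.
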