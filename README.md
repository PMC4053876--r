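# paqr — particulate air quality and population exposure assessment

`paqr` is an R toolkit for assessing particulate-matter (PM10 / PM2.5)
pollution and the population's exposure to it from gridded data. Ground
monitoring networks are sparse and uneven, so the concentration fields are
*estimated*: satellite aerosol retrievals (aerosol optical thickness AOT,
single scattering albedo SSA) and meteorological reanalysis fields (wind
speed, relative humidity, skin temperature, boundary-layer height), together
with latitude and longitude, drive a feed-forward neural network trained
against ground PM observations. The estimated fields are then turned into
air-quality indexes and province-level exposure statistics.

The package is aimed at researchers in environmental epidemiology and air
quality who need the whole chain — estimation, indexing, exposure — as
composable, scriptable pieces, plus a seeded synthetic-data generator so the
chain can be exercised and validated without any external data.

## The methods

**Concentration estimation.** Candidate inputs are screened by stepwise
regression (forward selection with backward elimination on partial-F
p-values). The estimator is a single-hidden-layer tanh network (default
8 inputs, 16 hidden nodes, linear output) trained by Levenberg–Marquardt
back-propagation: damped Gauss–Newton minimisation of the sum of squared
errors, with the classical damping schedule (λ₀ = 10⁻³, ×10 on a rejected
step, ÷10 on an accepted one, abort above 10¹⁰) and validation-based early
stopping. Training repeats over many random train/validation splits
(repeated random sampling); the model with the highest validation Pearson
*r* is kept. Accuracy is summarised by *r* and the mean absolute percentage
error, APE = 100/n · Σ|Y_est − Y_obs|/Y_obs.

**Individual indexes.** An individual air-quality index (IAQI) maps a
concentration through a breakpoint ladder by piecewise-linear
interpolation; the shipped ladders are the Chinese AQI standard's 24-hour
PM2.5 and PM10 tables (index 0–500), supplied as editable data.

**Composite particulate index (PAQI).** Individual indexes I_i get
index-proportional weights Q_i = I_i / Σ_j I_j. Extreme weights are counted
(s = #{Q_i < 0.05}, t = #{Q_i > 0.5}); when both extremes are present — a
dust-storm-like dominance pattern where one pollutant's index dwarfs the
other — the near-zero weights are truncated and the rest renormalised to
P_i, so PAQI = Σ P_i·I_i follows the dominant pollutant instead of being
diluted. The scheme accepts any number of particulate fractions ≥ 2.

**Population exposure.** Over each zone (province) of a zone mask, with
PM_i the cell concentration and P_i the cell population:
per-capita PC-PM2.5 = Σ PM_i·P_i / n (n = valid cells in the zone), and
population-weighted PW-PM2.5 = Σ PM_i·P_i / Σ P_i.

## Worked example

```r
library(paqr)

cfg <- sim_config(seed = 1)          # 40x40 deg/10 grid, 300 stations
sim <- simulate_all(cfg)             # predictors, truth, population, zones

fit <- train_lm(sim$stations_pm25, n_runs = 50, seed = 1)
glance(fit$report)
#>   n_runs split_fraction best_run best_r best_ape mean_r n_diverged
#> 1     50            0.8       16  0.986     9.94  0.969          0
```

The best of 50 random-sampling runs reaches validation r = 0.986 with a
9.9% mean absolute percentage error against held-out stations. Predicting
the grid and indexing it:

```r
pred <- predict_grid(fit$model, sim$fields)
i25 <- iaqi_grid(pred, default_breakpoints("PM2.5"))
i25
#> <grid_field IPM2.5> 40 x 40 cells, 0 masked
#>   values in [37.36, 344.4]

paqi(c(PM10 = 480, PM2.5 = 20))
#> <index_bundle> PAQI = 480 (s = 1, t = 1)
```

The dust-storm configuration (PM10 index 480 dominating a PM2.5 index of
20) triggers the extreme-weight truncation: the composite equals the
dominant index rather than the diluted weighted mean. Finally, provincial
exposure:

```r
zonal_report(pred, sim$population, sim$zones)
#>    zone zone_name  n_valid_cells total_population pc_pm25 pw_pm25 rank_pc rank_pw
#> 1     1 province_1           132           26723.  25445.   126.        2       3
#> 7     7 province_7           193           32877.  29825.   175.        1       1
#> ...
```

`pw_pm25` is the mean concentration a resident of the zone experiences
(µg/m³); `pc_pm25` additionally scales with how many people live there, so
small, dense, polluted zones rank high on it. `autoplot()` methods produce
maps of any `grid_field`, run diagnostics for training reports and
zone-level comparisons of the two exposure statistics.

A command-line front-end covering the same pipeline
(`simulate | train | predict | iaqi | paqi | exposure | run-all | validate`)
is installed at `system.file("cli", "paqtool.R", package = "paqr")`.

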