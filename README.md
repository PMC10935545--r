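# trenchshield

Agent-based simulation and single-cell analysis of **collective
hydrogen-peroxide shielding** in *E. coli* mother-machine trenches.

Cells in a dead-end microfluidic trench scavenge H2O2 flowing in from
the open end. Each scavenging cell attenuates the concentration
reaching the cells behind it, so with cells ordered from the open end
the local concentration at cell *i* is

    c_i = c0 * prod_{j<i} (1 - f_j),     f_j = 1 - exp(-sigma * S_j * E_j)

with `S_j = 2 pi r L` the cell's surface area and `E_j` its enzyme
level — surface-area scaling because scavenging is diffusion-limited
at the cell envelope (Damköhler number `k L / v ≈ 4e3`). An induced
wild-type cell removes about a third of the incoming peroxide, so the
concentration falls roughly exponentially with barrier-cell count and
a mother cell's stress response is determined by the number and
morphology of its neighbours, not by its own state.

The package provides, as plain R functions:

* `sim_config()` / `scenario()` / `simulate_trenches()` — the
  mechanistic simulator (growth, delayed OxyR induction with negative
  feedback, saturable basal scavenging, division sizer with content
  partitioning, filamentation checkpoint, priming-dependent death,
  Poisson mismatch foci), emitting one long-format track table per run;
* `write_tracks()` / `read_tracks()` / `validate_tracks()` — stable
  CSV I/O with structural validation;
* `build_feature_matrix()` — the 126-feature mother-cell matrix
  (7 statistics x 9 series x 2 epochs) plus the response-peak label;
* `fit_peak_regressor()` / `barrier_only_model()` /
  `train_classifier()` — 100-tree random forests with the
  `A = 1 - mean(|pred - obs| / obs)` accuracy metric and grouped
  mean-decrease-impurity importances;
* `calibrate()` / `infer_attenuation()` / `gradient_analysis()` —
  intensity-to-concentration calibration and per-barrier-cell
  attenuation inference;
* `cross_correlation_lag()`, `lineage_correlations()`,
  `sister_divergence()`, `decay_analysis()`, `classify_fate()`,
  `mismatch_rate()` — timing, memory, fate and mutagenesis analyses.

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `05_fates_memory_mutagenesis.R`) that run the whole
study over simulated data and write tables under `results/`.

## Worked example

```r
library(trenchshield)

cfg <- sim_config(n_trenches = 200, seed = 1)
sch <- treatment_schedule(0, 300, 100, t_min = -135, t_max = 300)
tt  <- simulate_trenches(cfg, sch)      # ~220k rows, a few seconds

# occupancy and the response of the mother cells
occ <- tt[, .N, by = .(trench_id, frame)]
mean(occ$N)                             # 7.58 cells per trench
m <- tt[cell_index == 0]
detect_peak(m[trench_id == 1, time], m[trench_id == 1, reporter])
#> $peak_time [1] 24        $peak_amplitude [1] 1341

# features and the prediction model (one concentration here)
fm  <- build_feature_matrix(tt)
length(feature_columns(fm))             # 126
rep <- fit_peak_regressor(fm, seed = 1)
rep
#> random-forest peak regressor: 126 features, 160 train / 40 test
#>   accuracy A = 0.914
#>   barrier share = 0.783, mother share = 0.217
#>   top-2 share = 0.414 (barrier_cum_area.median.treated, barrier_cum_area.mean.treated)
```

Running the full mixed-concentration study (4,000 mothers across
37.5–100 µM, `analysis/04_prediction_model.R`) prints

```
accuracy A = 0.709, barrier share = 0.782, top-2 = 0.509
barrier-only model (56 features): A = 0.709 (full model 0.709)
concentration classifier: 39% correct (chance 20%)
```

— the response magnitude of a mother cell is predicted to ~71%
accuracy from morphology and environment features alone, barrier-cell
features carry ~78% of the predictive power, and a model with no
mother features at all does just as well. The gradient analysis
(`analysis/03_gradient_calibration.R`) prints

```
calibration: slope 68.4 a.u./uM, intercept 49 a.u., R2 0.994
per-barrier-cell attenuation f = 0.337 (95% CI 0.292-0.364)
Damkohler number (catalase vs envelope diffusion): 4050
```

i.e. each wild-type barrier cell removes about a third of the local
peroxide, inferred back from reporter intensities exactly as one
would from microscopy data.

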