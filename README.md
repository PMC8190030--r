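# scfs — single-cell force spectroscopy simulation and rupture-force analysis

`scfs` is an R package for analyzing AFM single-cell force spectroscopy
(SCFS) retract curves and for generating physically grounded synthetic ones.
In SCFS a live cell attached to the cantilever is pressed onto a second cell
and retracted at constant velocity; the retract force trace shows abrupt
upward steps where individual adhesion bonds rupture (*jumps*) and
constant-force plateaus where membrane tethers are pulled and then detach
(*tethers*). The height of each jump times the cantilever spring constant is
a rupture force, and the distribution of rupture forces across conditions,
pulling velocities and drug treatments quantifies cell–cell adhesion.

The package covers the full measurement chain:

- **Synthetic curve generator** — Bell–Evans slip-bond ruptures under ramp
  loading through an effective stiffness, constant-force membrane-tether
  plateaus with exponential detach lengths, Gaussian deflection noise and
  linear baseline drift; every curve carries its ground-truth event list.
- **Thermal-tune calibration** — synthetic cantilever thermal records plus
  two spring-constant estimators (equipartition with an
  autocorrelation-aware confidence interval, and a simple-harmonic-oscillator
  PSD fit).
- **Detection** — baseline/drift correction, contact-point location,
  a residual-normalized two-window step statistic with a geometric guard
  against slope-kink artifacts, and jump/tether classification from the
  pre-step loading slope.
- **Statistics** — pooled condition datasets, true quartiles, fixed-width
  histograms, velocity trends, and an exact (tie-correct, enumerated)
  Mann–Whitney rank-sum test with a tie-corrected normal approximation for
  large samples.
- **Pipeline** — a seeded end-to-end synthetic study runner
  (condition × treatment × velocity grid), an analysis-only runner for
  directories of stored curves, provenance manifests, and a thin CLI
  (`exec/scfs` with `simulate | calibrate | detect | summarize | compare |
  study` subcommands).

## Core model

A bond loaded at constant rate `r = k_eff · v` survives to force `F` with

    S(F) = exp[ (k0·kBT / (x_beta·r)) · (1 − exp(F·x_beta / kBT)) ]

where `k0` is the unstressed off-rate (1/s), `x_beta` the distance to the
transition state (nm) and `kBT` the thermal energy (pN·nm). The most
probable rupture force is `F* = (kBT/x_beta)·ln(r·x_beta/(k0·kBT))`.
Condition presets fix `x_beta = 0.3` nm and solve `k0` so that the analytic
median at 3 µm/s matches each cell pairing's reference median; treatment
presets (vehicle, calcium chelation, actin depolymerization, myosin
inhibition) modify the bond parameters accordingly. Units everywhere: pN,
nm, s, µm/s.

## Worked example

Simulate one fibroblast–fibroblast curve, detect and classify its events,
and compare against ground truth:

```r
library(scfs)
out <- simulate_retract_curve(preset_condition("NF-NF", velocity_v = 3, seed = 5))
det <- process_curve(out$curve)
det
#> <scfs_detection> NF-NF: 3 events (2 jumps, 1 tethers)
det$events[, c("index", "separation_nm", "force_pN", "class", "loading_rate_pN_per_s")]
#>   index separation_nm force_pN  class loading_rate_pN_per_s
#> 1   241       61.4510 38.41859 tether              414.7444
#> 2   628      641.9678 41.84540   jump              609.1071
#> 3  1347      1720.5789 61.75224  jump              574.3490
out$truth[, c("index", "force_pN", "class")]
#>   index force_pN  class
#> 1   241 30.00000 tether
#> 2   628 42.48016   jump
#> 3  1347 68.43727   jump
```

A velocity series over a small synthetic study (2 maps × 24 curves per
velocity) shows the expected monotone increase of the median rupture force:

```r
study <- run_synthetic_study(conditions = "NF-NF", velocities = c(3, 5, 7.5, 10),
                             n_maps = 2, n_curves = 24, seed = 42)
study$table[, c("velocity_um_s", "n", "median_pN", "q25_pN", "q75_pN")]
#>   velocity_um_s   n median_pN   q25_pN   q75_pN
#> 1           3.0 141  51.62486 38.25186 59.63394
#> 2           5.0 141  58.72099 45.97094 70.16073
#> 3           7.5 132  64.01651 48.85847 74.47837
#> 4          10.0 110  69.36200 59.55708 77.98700
velocity_trend(c(3, 5, 7.5, 10), study$table$median_pN)
#> <velocity_series> 4 velocities, slope 2.47 pN/(um/s), spearman rho 1.000
```

Spring-constant calibration from a synthetic thermal record:

```r
rec <- simulate_thermal_deflection(k = 60, duration = 10, seed = 3)
estimate_k_equipartition(rec)
#> <k_estimate> k = 59.086 pN/nm (CI 58.409-59.766), method: equipartition
```

## Command line

```sh
exec/scfs simulate  --out curves --condition NF-NF --velocity 3 --seed 1
exec/scfs detect    --in curves --out results
exec/scfs study     --out study --conditions NF-NF,DF-DF --treatments none,ML7 \
                    --velocities 3 --n-maps 2 --seed 1
```

Detection parameters can be supplied in a TOML file (`--config params.toml`,
keys matching `detection_params()`) with individual flag overrides. Exit
codes: 0 success, 2 config error, 3 data error, 4 internal error.

## License

MIT (see `LICENSE`).
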