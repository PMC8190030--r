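---
title: "Methods: synthetic single-cell force spectroscopy and rupture-force analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic single-cell force spectroscopy and rupture-force analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfs)
```

This vignette documents the models, algorithms and numerical choices behind
`scfs`. The package analyzes AFM single-cell force spectroscopy (SCFS)
retract curves — records of cantilever deflection versus piezo position taken
while a cell bound to the cantilever is pulled off a second cell — and ships
a physics-based generator of such curves so that every analysis stage can be
validated against known ground truth.

Units throughout: force in pN, length in nm, time in s, velocity in µm/s,
stiffness in pN/nm. The thermal energy scale is
`kBT(T)` with `kB = 1.380649e-2` pN·nm/K, i.e. `r round(kBT(310.15), 4)`
pN·nm at 310.15 K.

## 1. The generative model

A simulated cycle (`simulate_retract_curve()`) consists of an approach ramp,
a constant-force dwell, and the retract segment that carries all the physics.
The retract force trace is a sum of four terms:

1. **Contact unloading.** A repulsive ramp `max(0, F_max − κ·g)` where `g` is
   piezo travel and `κ = 10` pN/nm is the contact stiffness (cell-body
   compliance dominates the cantilever, hence the shallow slope). With the
   default 300 pN maximum load the unload spans 30 nm.

2. **Bond ruptures.** A Poisson number (`lambda = 3`) of independent bonds
   engage at separations drawn uniformly from 0–1500 nm and load through an
   effective stiffness `k_eff = 0.2` pN/nm — cantilever and two cell bodies
   in series, far softer than the cantilever itself. Each bond ruptures at a
   force drawn from the Bell–Evans ramp-loading distribution (section 2) at
   loading rate `r = k_eff · v`, then the trace steps up by exactly that
   force. Rupture forces are the deliverable of the whole pipeline, so the
   step height is exact by construction.

3. **Membrane tethers.** A Poisson number (`lambda = 1`) of tethers each pull
   at a constant plateau (30 pN) from the contact point to an exponentially
   distributed detach length (mean 500 nm), then release in one step.
   Constant-force plateaus are the defining signature of lipid tethers pulled
   from the membrane at constant velocity; no worm-like-chain elasticity is
   modeled (a stated non-goal).

4. **Noise and drift.** White Gaussian deflection noise (`deflection_sd =
   0.1` nm, i.e. 6 pN of force noise at `k = 60` pN/nm) and a linear baseline
   tilt (`drift_slope = 0.001` pN per nm of travel).

Event positions are pushed apart to `min_event_spacing_nm = 60` nm — and away
from the contact edge — because two drops inside one detector window, or a
drop inside the contact unload, are not resolvable by any windowed detector;
the spacing is enforced on positions only, never on the sampled forces.
Ground truth (`$truth`) records each event's first post-step sample index,
separation, realized force and class.

What the generator deliberately does **not** emulate: viscoelastic cell
rheology, tether force–velocity dependence, bond maturation during the dwell,
multiple-bond cooperative cascades, or instrument artifacts beyond linear
drift.

## 2. Bell–Evans rupture forces

A slip bond with unstressed off-rate `k0` and transition-state distance
`x_beta` loaded at constant rate `r` survives to force `F` with probability

$$S(F) = \exp\!\Big[\frac{k_0\,k_BT}{x_\beta\,r}\Big(1 - e^{F x_\beta / k_BT}\Big)\Big].$$

`pbell()`, `dbell()` implement the distribution; `qbell()` inverts it in
closed form using `log1p` for accuracy in both tails, and
`sample_rupture_force()` draws by inverse transform, so determinism follows
from the RNG stream alone. The most probable force is
`bell_mode() = (kBT/x_beta)·ln(r·x_beta/(k0·kBT))`, clamped at zero in the
near-equilibrium regime. `bell_k0_for_median()` solves the median identity
for `k0` with `expm1`, which is how condition presets are calibrated: each
cell-pairing preset sets `k0` so that the analytic median at 3 µm/s equals
that pairing's reference median, leaving `x_beta = 0.3` nm shared.

Note the velocity series produced this way is log-linear in loading rate, yet
over the 3.3× velocity range used here it is statistically indistinguishable
from a straight line; the package reports the nonparametric (Spearman) trend
and fits a straight line for slope only, without claiming either functional
form.

## 3. Thermal calibration

`simulate_thermal_deflection()` generates cantilever thermal motion as a
discretized simple harmonic oscillator (SHO, default `f0 = 2` kHz, `Q = 3`)
whose variance is set by equipartition: `k·⟨d²⟩ = kBT`. Sampling must
satisfy `fs > 2·f0`.

Two estimators recover the spring constant:

- `estimate_k_equipartition()`: `k = kBT / var(d)` after removing a linear
  trend. The confidence interval uses an effective sample size from the
  integrated autocorrelation time, since SHO samples are strongly correlated
  at 20 kHz.
- `fit_sho_psd()`: Welch-averaged periodogram fit of the SHO line shape
  (Lorentzian-like amplitude response) by nonlinear least squares; `k` comes
  from the integrated spectrum. At least 50 spectral averages are required.

Both accept an optional first-mode shape correction factor (default 1, i.e.
no correction is applied unless requested).

## 4. Detection

`process_curve()` composes four stages.

**Baseline.** `correct_baseline()` fits a straight line to the final 25 % of
the retract — farthest from the surface, assumed event-free — and subtracts
it, removing offset and drift; force is `k` times the corrected deflection.
The noise scale `baseline_sd` is the robust SD (1.4826 × MAD) of the
corrected baseline region.

**Contact point.** `find_contact_point()` takes the last sample whose
running-mean force exceeds `+3·baseline_sd` (repulsive); curves that start
off-contact fall back to the first sample and are flagged. Tip–sample
separation is `(z_contact − z) − d`, i.e. piezo travel corrected for
cantilever bending.

**Step detection.** `detect_steps()` slides two `window_w = 15`-sample
windows along the force trace. At each split both windows are fitted with
straight lines (vectorized via cumulative sums), and the step estimate
`delta` is the gap between the two fits extrapolated to the split. Its
standard error comes from the windows' residual variances:

$$\mathrm{SE}^2 = \frac{\mathrm{RSS}_\mathrm{pre} + \mathrm{RSS}_\mathrm{post}}{w-2}
\Big(\frac{1}{w} + \frac{(w/2)^2}{S_{tt}}\Big), \qquad S_{tt} = \frac{w(w^2-1)}{12}.$$

The statistic `t = delta/SE` is a Welch-type t on *detrended* windows.
Detrending is essential: a loaded bond ramp has a steep slope whose spread
would both inflate a raw-SD denominator and cancel part of the mean
difference, hiding small ruptures that are plainly discontinuous. In the
noise-free limit the residuals vanish and any discontinuity gives an
infinite statistic at its exact index, which is why the detector is provably
equivalent to an exact finite-difference scan on noise-free curves (the
package's strongest self-test).

Two guards make the noise-free equivalence exact in floating point:

- a float-epsilon guard zeroes the statistic when `delta` is below `1e-8`
  of the trace's dynamic range (rounding on exactly linear ramps);
- a **kink guard**: a continuous slope kink (the contact-ramp corner, or a
  bond engaging mid-window) makes the two extrapolated fits disagree even
  though the trace has no step. For a single kink the fictitious gap is at
  most `(w − 1/2)/3` times the fitted slope difference — the worst case puts
  the breakpoint one sample inside the far window edge — and same-sign kinks
  superpose within the same bound, so candidates must satisfy
  `delta > (w − 1/2)/3 · |slope_post − slope_pre|`. The constant follows
  from the window geometry alone. Without it, the 14.7 pN-per-sample corner
  of the contact unload fakes steps of up to ~29 pN.

Candidates exceeding `threshold_theta = 6` undergo non-maximum suppression
(radius `min_separation_events = 15` samples, ties to the earlier index),
and events with step force below `min_force_factor · baseline_sd = 3σ` are
discarded. With Gaussian noise `SE ≈ 0.73σ`, so the effective detection
floor is `6 · 0.73σ ≈ 4.4σ` — about 13 pN at the benchmark noise of 3 pN —
and the per-split false-positive rate of a 6-SE threshold keeps whole
event-free curves clean at the ~99 % level.

**Force error budget.** The detected step height is the fit-gap `delta`
itself. Its sampling variance under white noise is `2σ²·(1/w + (w/2)²/Stt)
≈ 0.53σ²`, i.e. an RMSE of `0.73σ ≈ 2.2 pN` at benchmark noise — the
dominant term; systematic localization error contributes < 0.2 pN. This is
why the observed benchmark force RMSE sits near 2.2 pN.

**Classification.** `classify_events()` fits the force-versus-separation
slope over up to `slope_window = 100` samples before each step, truncated at
the previous event and at the contact point. A *jump* (bond rupture) call
requires positive evidence of loading: `|slope| ≥ slope_min = 0.05` pN/nm
*and* `|slope| ≥ 2·SE(slope)`; otherwise the event is a *tether*
(flat plateau before the drop). The long window is needed because a slope of
a few hundredths of a pN/nm must be resolved against 6 pN noise; the 2·SE
rule prevents short noisy windows from producing spurious jumps. The local
loading rate is `|slope| · v`. The rupture force is the spring constant
times the deflection step height, exactly.

## 5. Statistics

Only jump forces enter the statistics (tethers are detected and classified
but not pooled — a stated non-goal). `pool_condition()` collects them per
condition × treatment × velocity; `summarize_forces()` reports n, median,
true type-7 quartiles and a fixed-width histogram (10 pN bins);
`velocity_trend()` gives the Spearman rank correlation of medians versus
velocity plus a least-squares slope.

`wilcoxon_ranksum()` is a two-sided Mann–Whitney U test. For small samples
(smaller group ≤ 10 and a feasible enumeration count) it computes the exact
permutation distribution of the midrank U statistic — correct under ties,
matching a brute-force permutation oracle to 1e-12. Larger samples use the
tie-corrected normal approximation with continuity correction. Significance
stars follow `* p < 0.05`, `** p < 0.005`. Comparisons are run on pooled
forces; per-map medians remain available through the per-map datasets.

## 6. Presets and the synthetic study

`preset_condition()` encodes cell-pairing presets (normal, EMT-shifted and
epithelial pairings) whose `k0` reproduce each pairing's reference median at
3 µm/s, plus treatments: `DMSO` (vehicle, identical to control), `EGTA`
(calcium chelation: binding ablated, `lambda = 0.02` for both bonds and
tethers, so ≈ 96 % of curves are event-free), `cytochalasinD` (actin
depolymerization: medians scaled down per pairing) and `ML7` (myosin-II
inhibition: raises the median of the fibroblast–fibroblast EMT pairing
only). `preset_benchmark()` is a detection-oriented configuration (median
100 pN, noise 0.05 nm → SNR ≥ 5) used by the quality-gate tests.

`run_synthetic_study()` simulates maps for every condition × treatment ×
velocity cell (default 24 curves/map), detects, pools, summarizes and — when
several treatments are present — compares treatments pairwise within each
condition and velocity. All randomness descends from one seed through
deterministic child seeds, so any single curve of a study can be regenerated
in isolation. Runs can be written to disk (`events.tsv`, `table.tsv`,
`summary.json`, `comparisons.tsv`, `config.json`, `manifest.json`,
`run.log`); the manifest carries the package version, seed and a hash of the
canonical-JSON config, and identical configs hash identically.
`run_analyze()` applies the identical analysis half to a directory of stored
curve TSVs, skipping unreadable files with a warning and aborting if more
than 20 % fail.

## 7. Worked example

```{r example}
study <- run_synthetic_study(conditions = "NF-NF",
                             velocities = c(3, 5, 7.5, 10),
                             n_maps = 2, n_curves = 24, seed = 42)
study$table[, c("velocity_um_s", "n", "median_pN", "q25_pN", "q75_pN")]
velocity_trend(c(3, 5, 7.5, 10), study$table$median_pN)
```

## 8. Limitations

- Rupture forces are reported per step; the maximum pull-off force of a
  multi-bond cascade is not a separate deliverable.
- Tether plateaus are ideal constant-force segments; real tethers show
  velocity-dependent plateau forces and elastic onsets.
- The detector's floor (~4.4 × baseline noise) means genuinely small
  ruptures below ~13 pN at benchmark noise are invisible by design, and
  steps smaller than the kink-guard scale (~1.5 pN per engaged bond,
  noise-free) are suppressed in favor of continuity.
- Calibration implements the thermal route only (equipartition + SHO
  spectral fit); hydrodynamic-geometry methods are out of scope.
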