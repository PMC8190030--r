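# Condition presets.  The generator is calibrated so that, at the reference
# pulling velocity of 3 um/s, the median of the Bell-Evans rupture-force
# distribution equals a per-condition target median taken from published
# SCFS measurements of fibroblast (NF normal, SF scar, DF Dupuytren
# myofibroblast) and MDCK epithelial cell-cell adhesion.  Treatments modify
# the target: the cytochalasin D preset scales it by the per-condition
# treated/control ratio of the same measurements, the ML-7 preset raises it
# for DF-DF only (the one pairing where myosin inhibition strengthened
# adhesion), DMSO vehicle is identical to control, and EGTA (calcium
# chelation) suppresses bond formation itself rather than the force scale.

.conditions <- c("NF-NF", "SF-SF", "DF-DF", "MDCK-MDCK",
                 "NF-MDCK", "SF-MDCK", "DF-MDCK")
.velocities <- c(3, 5, 7.5, 10)

# median rupture force (pN) per condition x pulling velocity (um/s)
.median_by_velocity <- matrix(c(
  51.91,  73.40,  97.18, 117.39,   # NF-NF
  45.21,  74.22, 103.28, 128.51,   # SF-SF
  35.71,  58.23,  83.54, 103.05,   # DF-DF
  75.51,  98.48, 124.08, 149.68,   # MDCK-MDCK
  55.85,  70.48,  91.44, 111.28,   # NF-MDCK
  39.68,  68.19,  92.36, 106.62,   # SF-MDCK
  46.70,  63.62,  83.20,  99.42),  # DF-MDCK
  nrow = 7, byrow = TRUE,
  dimnames = list(.conditions, as.character(.velocities)))

# median rupture force (pN) in the drug experiments: control / DMSO / drug
.median_cytoD <- matrix(c(
  61.86, 60.24, 31.06,
  58.41, 48.34, 30.47,
  48.41, 45.64, 25.65,
  75.61, 75.24, 43.21,
  57.04, 64.70, 25.54,
  56.77, 57.19, 14.98,
  60.13, 68.42, 23.36),
  nrow = 7, byrow = TRUE,
  dimnames = list(.conditions, c("control", "DMSO", "cytochalasinD")))

.median_ML7 <- matrix(c(
  58.81, 52.04, 48.87,
  66.20, 53.12, 48.98,
  53.19, 45.49, 99.69,
  69.71, 67.22, 69.69,
  52.06, 54.74, 54.41,
  48.95, 53.87, 41.44,
  48.35, 47.05, 52.32),
  nrow = 7, byrow = TRUE,
  dimnames = list(.conditions, c("control", "DMSO", "ML7")))

#' Reference median rupture forces used to calibrate the presets
#'
#' Long-format table of the per-condition median rupture forces (pN) that the
#' condition presets target: one block per pulling velocity for untreated
#' measurements, and control/DMSO/drug blocks for the cytochalasin D and ML-7
#' treatment series.
#'
#' @return data frame with columns `condition`, `series`, `treatment`,
#'   `velocity_um_s`, `median_pN`
#' @export
reference_medians <- function() {
  vel <- data.frame(condition = rep(.conditions, times = length(.velocities)),
                    series = "velocity",
                    treatment = "none",
                    velocity_um_s = rep(.velocities, each = 7),
                    median_pN = as.vector(.median_by_velocity),
                    stringsAsFactors = FALSE)
  drug <- function(mat, series) {
    data.frame(condition = rep(.conditions, times = 3),
               series = series,
               treatment = rep(colnames(mat), each = 7),
               velocity_um_s = 3,
               median_pN = as.vector(mat),
               stringsAsFactors = FALSE)
  }
  rbind(vel, drug(.median_cytoD, "cytochalasinD"), drug(.median_ML7, "ML7"))
}

#' Benchmark preset for detector quality gating
#'
#' A high signal-to-noise configuration for measuring detector recall,
#' precision and force error: the Bell off-rate is solved so the median
#' rupture force is 100 pN at 3 um/s, the tether plateau is 30 pN, and the
#' deflection noise is 0.05 nm (baseline force noise 3 pN at 60 pN/nm), so
#' essentially every generated step is at least five baseline standard
#' deviations high.  With `noise_sd = 0`, curves are noise-free and the
#' detector can be checked index-by-index against an exact finite-difference
#' scan.
#'
#' @param seed RNG seed
#' @param noise_sd deflection noise, nm
#' @param velocity_v pulling velocity, um/s
#' @param ... overrides passed to [sim_config()]
#' @return a [sim_config()]
#' @export
preset_benchmark <- function(seed = 1L, noise_sd = 0.05, velocity_v = 3, ...) {
  meta <- curve_metadata(velocity_v = velocity_v,
                         condition_label = "benchmark", curve_id = "benchmark")
  k_eff <- 0.2
  k0 <- bell_k0_for_median(100, x_beta = 0.3, r = k_eff * .um_s_to_nm_s(3),
                           kbt = kBT(meta$temperature))
  sim_config(metadata = meta,
             bond = bond_model(lambda = 3, k0 = k0, x_beta = 0.3, k_eff = k_eff),
             tether = tether_model(lambda = 1, plateau_force = 30),
             noise = noise_model(deflection_sd = noise_sd, drift_slope = 0.001),
             seed = seed, ...)
}

#' Build the simulation preset for a condition and treatment
#'
#' Returns a [sim_config()] whose Bell off-rate `k0` is solved in closed form
#' so that the median of the rupture-force distribution at the calibration
#' velocity (3 um/s) equals the condition's reference median, scaled by the
#' treatment effect.  Because the loading rate is `k_eff * v`, medians then
#' increase monotonically with pulling velocity.  Treatment effects:
#' `"none"` and `"DMSO"` leave the target unchanged; `"cytochalasinD"`
#' multiplies it by the per-condition treated/control ratio (always < 1);
#' `"ML7"` multiplies it by the DF-DF treated/control ratio for DF-DF and
#' leaves every other pairing unchanged; `"EGTA"` keeps the force scale but
#' sets both event rates to ~0 (`lambda = 0.02` for bonds and tethers), so
#' nearly all curves are event-free.
#'
#' @param name preset name: `"<condition>"` or `"<condition>-<treatment>"`,
#'   e.g. `"NF-NF"`, `"DF-DF-ML7"`, `"NF-NF-EGTA"`; conditions are NF-NF,
#'   SF-SF, DF-DF, MDCK-MDCK, NF-MDCK, SF-MDCK, DF-MDCK
#' @param velocity_v pulling velocity of the generated curves, um/s
#' @param seed RNG seed stored in the config
#' @param ... overrides passed on to [sim_config()]
#' @return a [sim_config()]; the calibrated target median (pN) is attached as
#'   attribute `target_median`
#' @examples
#' cfg <- preset_condition("NF-NF")
#' attr(cfg, "target_median")  # 51.91 pN at 3 um/s
#' @export
preset_condition <- function(name, velocity_v = 3, seed = 1L, ...) {
  treatments <- c("none", "EGTA", "DMSO", "cytochalasinD", "ML7")
  condition <- name
  treatment <- "none"
  for (tr in treatments[-1]) {
    suffix <- paste0("-", tr)
    if (endsWith(name, suffix)) {
      condition <- substr(name, 1, nchar(name) - nchar(suffix))
      treatment <- tr
      break
    }
  }
  if (!condition %in% .conditions)
    stop(sprintf("preset_condition: unknown preset '%s'", name))

  base_median <- .median_by_velocity[condition, "3"]
  factor <- switch(treatment,
                   none = 1, DMSO = 1, EGTA = 1,
                   cytochalasinD = .median_cytoD[condition, "cytochalasinD"] /
                     .median_cytoD[condition, "control"],
                   ML7 = if (condition == "DF-DF")
                     .median_ML7["DF-DF", "ML7"] / .median_ML7["DF-DF", "control"]
                   else 1)
  target <- base_median * factor

  meta <- curve_metadata(velocity_v = velocity_v,
                         condition_label = condition,
                         treatment_label = treatment,
                         curve_id = name)
  k_eff <- 0.2                     # soft cell dominates the series compliance
  r_cal <- k_eff * .um_s_to_nm_s(3)   # calibration loading rate, pN/s
  k0 <- bell_k0_for_median(target, x_beta = 0.3, r = r_cal,
                           kbt = kBT(meta$temperature))
  # calcium chelation abolishes cadherin bonds almost entirely and thins the
  # overall event count, tethers included: the preset is defined to leave the
  # vast majority of curves with no event at all
  lambda_b <- if (treatment == "EGTA") 0.02 else 3
  teth <- if (treatment == "EGTA") tether_model(lambda = 0.02) else tether_model()
  cfg <- sim_config(metadata = meta,
                    bond = bond_model(lambda = lambda_b, k0 = k0,
                                      x_beta = 0.3, k_eff = k_eff),
                    tether = teth,
                    seed = seed, ...)
  attr(cfg, "target_median") <- target
  cfg
}
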