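#' Per-curve acquisition metadata
#'
#' Collects the acquisition settings attached to one approach/retract cycle.
#' Defaults reproduce the typical SCFS protocol for cell-cell adhesion
#' measurements: a soft tipless cantilever of nominal spring constant
#' 60 pN/nm, approach/retract velocity 3 um/s, 3 nN maximum load, 2 s contact
#' dwell, at 37 C.
#'
#' @param spring_constant_k cantilever spring constant, pN/nm (> 0)
#' @param velocity_v approach/retract velocity, um/s (> 0)
#' @param max_load maximum loading (contact) force, pN
#' @param dwell_time contact dwell time, s (>= 0)
#' @param sampling_rate sampling rate, Hz (> 0)
#' @param temperature temperature, K
#' @param condition_label cell-cell pairing label, e.g. `"NF-NF"`
#' @param treatment_label one of `"none"`, `"EGTA"`, `"DMSO"`,
#'   `"cytochalasinD"`, `"ML7"`
#' @param curve_id identifier of the curve
#' @return object of class `curve_metadata` (a named list)
#' @export
curve_metadata <- function(spring_constant_k = 60,
                           velocity_v = 3,
                           max_load = 3000,
                           dwell_time = 2,
                           sampling_rate = 2000,
                           temperature = 310.15,
                           condition_label = "unspecified",
                           treatment_label = "none",
                           curve_id = "curve") {
  stopifnot(spring_constant_k > 0, velocity_v > 0,
            sampling_rate > 0, dwell_time >= 0, temperature > 0)
  treatment_label <- match.arg(treatment_label,
                               c("none", "EGTA", "DMSO", "cytochalasinD", "ML7"))
  structure(list(spring_constant_k = spring_constant_k,
                 velocity_v = velocity_v,
                 max_load = max_load,
                 dwell_time = dwell_time,
                 sampling_rate = sampling_rate,
                 temperature = temperature,
                 condition_label = condition_label,
                 treatment_label = treatment_label,
                 curve_id = curve_id),
            class = "curve_metadata")
}

#' One AFM force-distance cycle
#'
#' The pipeline's atomic input: sampled piezo position and cantilever
#' deflection over an approach / dwell / retract cycle, plus acquisition
#' metadata.  Coordinate conventions: `z_position` is piezo extension in nm,
#' larger values meaning closer to the sample during approach; deflection is
#' in nm, positive when the cantilever is pushed away from the surface
#' (repulsive), so adhesive deflection during retract is negative.
#'
#' @param time sample times, s, monotone increasing
#' @param z_position piezo extension, nm; within the retract segment it must
#'   be monotone non-increasing (pulling away from the sample)
#' @param deflection cantilever deflection, nm
#' @param segment per-sample segment labels, each one of
#'   `"approach"`, `"dwell"`, `"retract"`; the retract segment must be
#'   non-empty
#' @param metadata a [curve_metadata()] object
#' @return object of class `force_curve`
#' @export
force_curve <- function(time, z_position, deflection, segment, metadata) {
  n <- length(time)
  if (length(z_position) != n || length(deflection) != n || length(segment) != n)
    stop("force_curve: time, z_position, deflection and segment must have equal length")
  if (n > 1 && any(diff(time) <= 0))
    stop("force_curve: time must be strictly increasing")
  if (!all(segment %in% c("approach", "dwell", "retract")))
    stop("force_curve: segment labels must be approach/dwell/retract")
  ret <- segment == "retract"
  if (!any(ret))
    stop("force_curve: retract segment is empty")
  zr <- z_position[ret]
  if (length(zr) > 1 && any(diff(zr) > 1e-9))
    stop("force_curve: z_position must be non-increasing within the retract segment")
  if (!inherits(metadata, "curve_metadata"))
    stop("force_curve: metadata must be a curve_metadata object")
  structure(list(time = as.numeric(time),
                 z_position = as.numeric(z_position),
                 deflection = as.numeric(deflection),
                 segment = as.character(segment),
                 metadata = metadata),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<force_curve> %s  [%s / %s]\n", m$curve_id,
              m$condition_label, m$treatment_label))
  cat(sprintf("  %d samples (%d retract), k = %g pN/nm, v = %g um/s, fs = %g Hz\n",
              length(x$time), sum(x$segment == "retract"),
              m$spring_constant_k, m$velocity_v, m$sampling_rate))
  invisible(x)
}

#' A force map: an ordered collection of force curves
#'
#' One force map groups the curves recorded over a grid position on a cell
#' monolayer; in the emulated protocol a map holds 24 curves, all sharing one
#' condition label.
#'
#' @param curves list of [force_curve()] objects sharing a condition label
#' @param map_id identifier
#' @return object of class `force_map`
#' @export
force_map <- function(curves, map_id = "map") {
  stopifnot(is.list(curves), length(curves) >= 1)
  if (!all(vapply(curves, inherits, logical(1), "force_curve")))
    stop("force_map: all elements must be force_curve objects")
  labels <- vapply(curves, function(cv) cv$metadata$condition_label, character(1))
  if (length(unique(labels)) != 1)
    stop("force_map: all curves in a map must share one condition label")
  structure(list(curves = curves, map_id = map_id), class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map> %s: %d curves [%s]\n", x$map_id, length(x$curves),
              x$curves[[1]]$metadata$condition_label))
  invisible(x)
}

#' Pool jump rupture forces into a condition dataset
#'
#' Collects the rupture forces of jump-class events (bond ruptures) into the
#' pooled population used for condition-level statistics.  Tether-class
#' events (membrane tether detachments) are excluded: only forces read from
#' abrupt jumps preceded by a loaded ramp enter the rupture-force population.
#' An empty result (no jumps, as under calcium chelation) is allowed.
#'
#' @param events a `rupture_events` data frame (see [process_curve()]), or any
#'   data frame with columns `class` and `force_pN`
#' @param condition_label,treatment_label,velocity_v labels of the pooled cell
#' @param n_curves,n_maps optional counts of contributing curves / maps
#' @return object of class `condition_dataset` with element `rupture_forces`
#'   (pN, jumps only)
#' @export
pool_condition <- function(events, condition_label, treatment_label = "none",
                           velocity_v = 3, n_curves = NA_integer_,
                           n_maps = NA_integer_) {
  stopifnot(is.data.frame(events))
  if (nrow(events) > 0) {
    stopifnot(all(c("class", "force_pN") %in% names(events)))
    forces <- events$force_pN[events$class == "jump"]
  } else {
    forces <- numeric(0)
  }
  if (any(forces <= 0)) stop("pool_condition: rupture forces must be positive")
  structure(list(condition_label = condition_label,
                 treatment_label = treatment_label,
                 velocity_v = velocity_v,
                 rupture_forces = as.numeric(forces),
                 n_curves = n_curves,
                 n_maps = n_maps),
            class = "condition_dataset")
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat(sprintf("<condition_dataset> %s / %s @ %g um/s: %d jump forces\n",
              x$condition_label, x$treatment_label, x$velocity_v,
              length(x$rupture_forces)))
  if (length(x$rupture_forces))
    cat(sprintf("  median %.2f pN (IQR %.2f-%.2f)\n",
                stats::median(x$rupture_forces),
                stats::quantile(x$rupture_forces, 0.25),
                stats::quantile(x$rupture_forces, 0.75)))
  invisible(x)
}
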