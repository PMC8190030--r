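# Rupture-event detection on retract curves: baseline/drift correction,
# contact-point location, two-window step detection, and classification of
# each step as a bond-rupture jump (loaded ramp before the drop) or a
# membrane-tether detachment (flat plateau before the drop).

#' Detection parameters
#'
#' @param window_w half-window of the two-window step statistic, samples
#' @param threshold_theta detection threshold on the two-window step
#'   statistic (the gap between the two windows' linear fits at the split,
#'   over the standard error of that gap)
#' @param min_force_factor events with step force below
#'   `min_force_factor * baseline_sd` are discarded
#' @param min_separation_events minimum spacing between detected events,
#'   samples (non-maximum suppression radius)
#' @param slope_min discriminant between jumps and tethers, pN/nm: events
#'   whose pre-step force/separation slope magnitude is at least `slope_min`
#'   are jumps, below are tethers
#' @param slope_window samples used for the pre-step slope fit (truncated at
#'   the previous event and at the contact point); longer than `window_w`
#'   because a slope of a few hundredths of a pN/nm must be resolved against
#'   baseline noise
#' @param baseline_fraction final fraction of the retract (farthest from the
#'   surface, assumed event-free) used for the baseline fit
#' @return object of class `detection_params`
#' @export
detection_params <- function(window_w = 15, threshold_theta = 6,
                             min_force_factor = 3, min_separation_events = 15,
                             slope_min = 0.05, slope_window = 100,
                             baseline_fraction = 0.25) {
  stopifnot(window_w >= 2, threshold_theta > 0, min_force_factor > 0,
            min_separation_events > 0, slope_min > 0,
            slope_window >= window_w,
            baseline_fraction > 0, baseline_fraction <= 0.5)
  structure(list(window_w = as.integer(window_w),
                 threshold_theta = threshold_theta,
                 min_force_factor = min_force_factor,
                 min_separation_events = as.integer(min_separation_events),
                 slope_min = slope_min,
                 slope_window = as.integer(slope_window),
                 baseline_fraction = baseline_fraction),
            class = "detection_params")
}

#' Baseline-correct a retract curve and convert deflection to force
#'
#' Fits a straight line (least squares) to the final `baseline_fraction` of
#' the retract segment -- the region farthest from the surface, assumed
#' event-free -- and subtracts it from the whole retract, removing offset and
#' linear drift.  Corrected deflection is converted to force via
#' `F = k * d`.  The baseline noise scale is the robust SD (1.4826 x median
#' absolute deviation) of the corrected baseline region.
#'
#' @param curve a [force_curve()]
#' @param params a [detection_params()]
#' @return object of class `processed_curve`: retract-only `z` (nm), `force`
#'   (pN), `deflection` (corrected, nm), `baseline_sd` (pN), metadata and
#'   provenance.  `separation` and `contact_index` are filled in by
#'   [find_contact_point()] / [process_curve()].
#' @export
correct_baseline <- function(curve, params = detection_params()) {
  stopifnot(inherits(curve, "force_curve"), inherits(params, "detection_params"))
  ret <- curve$segment == "retract"
  z <- curve$z_position[ret]
  d <- curve$deflection[ret]
  n <- length(z)
  n_base <- floor(n * params$baseline_fraction)
  if (n_base < 50)
    stop("correct_baseline: baseline region has fewer than 50 samples")
  idx_base <- (n - n_base + 1):n
  fit <- stats::lm.fit(cbind(1, z[idx_base]), d[idx_base])
  d_corr <- d - (fit$coefficients[1] + fit$coefficients[2] * z)
  k <- curve$metadata$spring_constant_k
  force <- k * d_corr
  structure(list(z = z, force = force, deflection = d_corr,
                 baseline_sd = stats::mad(force[idx_base]),
                 separation = NULL, contact_index = NA_integer_,
                 contact_flagged = FALSE,
                 metadata = curve$metadata, params = params),
            class = "processed_curve")
}

#' @export
print.processed_curve <- function(x, ...) {
  cat(sprintf("<processed_curve> %s: %d retract samples, baseline sd %.3g pN, contact @ %s\n",
              x$metadata$curve_id, length(x$force), x$baseline_sd,
              ifelse(is.na(x$contact_index), "?", x$contact_index)))
  invisible(x)
}

.running_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - w %/% 2, 1)
  hi <- pmin(lo + w - 1, n)
  lo <- pmax(hi - w + 1, 1)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Locate the contact point of a processed retract curve
#'
#' The contact point is the last retract sample (scanning from the free end
#' toward the surface-side start) at which the running-mean force exceeds
#' `+3 * baseline_sd` in the repulsive direction.  If the curve never shows a
#' repulsive region (it starts off-contact), the surface-side end is used and
#' the result is flagged.
#'
#' @param p a `processed_curve` from [correct_baseline()]
#' @return the contact sample index, with attribute `flagged` (logical)
#' @export
find_contact_point <- function(p) {
  stopifnot(inherits(p, "processed_curve"))
  w <- p$params$window_w
  sm <- .running_mean(p$force, w)
  thr <- 3 * p$baseline_sd
  above <- which(sm > thr)
  if (length(above) == 0) {
    idx <- 1L
    attr(idx, "flagged") <- TRUE
    return(idx)
  }
  idx <- max(above)
  attr(idx, "flagged") <- FALSE
  idx
}

# attach contact point and tip-sample separation s = (z_contact - z) - d
.add_separation <- function(p) {
  ci <- find_contact_point(p)
  p$contact_index <- as.integer(ci)
  p$contact_flagged <- isTRUE(attr(ci, "flagged"))
  p$separation <- (p$z[p$contact_index] - p$z) - p$deflection
  p
}

#' Detect candidate force steps in a processed retract curve
#'
#' Slides a two-window statistic along the retract force trace: at each
#' interior split the `window_w` samples before and after are fitted with
#' straight lines, and the gap between the two fits extrapolated to the split
#' (the step estimate) is normalized by its standard error computed from the
#' windows' residual variances -- a Welch-type t statistic on the detrended
#' windows, so loaded ramps do not mask the step.  In the noise-free limit
#' the residuals vanish and any discontinuity yields an infinite statistic at
#' its exact index, making the detector equivalent to a finite-difference
#' scan.  Candidates are splits where the statistic exceeds
#' `threshold_theta` in the force-release direction (force stepping up toward
#' the baseline) *and* whose step estimate exceeds the largest fictitious gap
#' a continuous slope kink inside one window could produce (the kink guard,
#' `(window_w - 1/2)/3` times the fitted slope difference); local maxima are
#' kept with at least `min_separation_events` spacing (ties keep the earlier
#' index), and candidates whose step force falls below
#' `min_force_factor * baseline_sd` are discarded.
#'
#' @param p a `processed_curve`
#' @param params a [detection_params()]; defaults to the parameters stored in
#'   `p`
#' @return data frame with columns `index`, `statistic`, `step_force_pN`,
#'   `step_height_nm`
#' @export
detect_steps <- function(p, params = p$params) {
  stopifnot(inherits(p, "processed_curve"))
  x <- p$force
  n <- length(x)
  w <- params$window_w
  if (n < 4 * w)
    stop("detect_steps: curve shorter than 4 * window_w samples")

  # Rolling linear fits of the two windows around every split point; the step
  # estimate is the gap between the fitted lines extrapolated to the split,
  # its standard error comes from the windows' residual (detrended) variance.
  # Detrending matters: a loaded bond ramp has a steep slope whose spread
  # would otherwise both inflate the denominator and cancel part of the mean
  # difference, hiding small ruptures that are plainly discontinuous.
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  csj <- cumsum(c(0, x * seq_len(n)))
  Stt <- w * (w^2 - 1) / 12                # centered index sum of squares
  cexp <- 1 / w + (w / 2)^2 / Stt          # extrapolation variance factor
  win_fit <- function(a) {                 # windows [a, a + w - 1]
    b <- a + w - 1
    Sy <- cs[b + 1] - cs[a]
    Sty <- (csj[b + 1] - csj[a]) - (a + b) / 2 * Sy
    slope <- Sty / Stt
    rss <- pmax(0, (cs2[b + 1] - cs2[a]) - Sy^2 / w - slope^2 * Stt)
    list(ybar = Sy / w, slope = slope, tbar = (a + b) / 2, rss = rss)
  }
  i <- (w + 1):(n - w + 1)
  pre <- win_fit(i - w); post <- win_fit(i)
  at <- i - 0.5
  delta <- (post$ybar + post$slope * (at - post$tbar)) -
    (pre$ybar + pre$slope * (at - pre$tbar))
  se <- sqrt((pre$rss + post$rss) / (w - 2) * cexp)
  tstat <- delta / se
  # noise-free limit: zero residuals around an unambiguous step give an
  # infinite statistic at the exact index
  tstat[se == 0] <- ifelse(delta[se == 0] > 0, Inf, 0)
  # guard against float-epsilon "steps" on exactly linear noise-free ramps
  tstat[delta <= 1e-8 * (max(x) - min(x))] <- 0

  # a slope kink (contact-ramp corner, bond engagement) with its breakpoint
  # inside one window makes the extrapolated fits disagree even though the
  # trace is continuous.  For a single kink the fictitious gap is at most
  # (w - 1/2)/3 times the fitted slope difference (worst case: breakpoint one
  # sample inside the far window edge), and same-sign kinks superpose within
  # the same bound, so a real discontinuity must clear that scale
  kink_guard <- (w - 0.5) / 3 * abs(post$slope - pre$slope)
  cand <- which(tstat >= params$threshold_theta & delta > kink_guard)
  if (length(cand) == 0)
    return(data.frame(index = integer(0), statistic = numeric(0),
                      step_force_pN = numeric(0), step_height_nm = numeric(0)))

  # non-maximum suppression, ties broken toward the earlier index
  ord <- cand[order(-tstat[cand], cand)]
  accepted <- integer(0)
  for (j in ord)
    if (!length(accepted) || all(abs(accepted - j) >= params$min_separation_events))
      accepted <- c(accepted, j)
  accepted <- sort(accepted)

  idx <- i[accepted]
  height <- delta[accepted]

  keep <- height >= params$min_force_factor * p$baseline_sd & height > 0
  k <- p$metadata$spring_constant_k
  data.frame(index = idx[keep],
             statistic = tstat[accepted][keep],
             step_force_pN = height[keep],
             step_height_nm = height[keep] / k)
}

#' Classify step candidates as jumps or tethers
#'
#' Fits the force-versus-separation slope over the `slope_window` samples
#' preceding each step (truncated so the fit does not reach past the previous
#' event or the contact point): a loaded ramp marks a bond-rupture jump, a
#' flat plateau marks a membrane-tether detachment.  A jump call requires
#' positive evidence of loading: the slope magnitude must reach `slope_min`
#' *and* twice its own standard error, so that short, noisy windows default
#' to the tether class instead of producing spurious jumps.  The rupture force is the cantilever spring
#' constant times the deflection step height (exactly, by construction), and
#' the local loading rate is the pre-step slope magnitude times the pulling
#' velocity.
#'
#' @param p a `processed_curve` with separation filled in (see
#'   [process_curve()])
#' @param candidates data frame from [detect_steps()]
#' @param params a [detection_params()]
#' @return data frame of class `rupture_events` with columns `curve_id`,
#'   `index`, `separation_nm`, `step_height_nm`, `force_pN`, `class`,
#'   `loading_rate_pN_per_s`, `pre_slope_pN_per_nm`
#' @export
classify_events <- function(p, candidates, params = p$params) {
  stopifnot(inherits(p, "processed_curve"), !is.null(p$separation))
  if (nrow(candidates) == 0) {
    ev <- data.frame(curve_id = character(0), index = integer(0),
                     separation_nm = numeric(0), step_height_nm = numeric(0),
                     force_pN = numeric(0), class = character(0),
                     loading_rate_pN_per_s = numeric(0),
                     pre_slope_pN_per_nm = numeric(0),
                     stringsAsFactors = FALSE)
    class(ev) <- c("rupture_events", "data.frame")
    return(ev)
  }
  w <- params$window_w
  v_nm_s <- .um_s_to_nm_s(p$metadata$velocity_v)
  idx_sorted <- sort(candidates$index)
  slope_fit <- vapply(candidates$index, function(ii) {
    lo <- ii - params$slope_window
    prev_ev <- idx_sorted[idx_sorted < ii]
    if (length(prev_ev))              # stay clear of the previous event's step
      lo <- max(lo, max(prev_ev) + w)
    if (!is.na(p$contact_index))    # guard against the contact unload tail
      lo <- max(lo, p$contact_index + w)
    lo <- min(lo, ii - w)             # never fewer than window_w samples
    lo <- max(lo, 1L)
    pre <- lo:(ii - 1)
    fit <- stats::lm.fit(cbind(1, p$separation[pre]), p$force[pre])
    sxx <- sum((p$separation[pre] - mean(p$separation[pre]))^2)
    s2 <- sum(fit$residuals^2) / max(length(pre) - 2, 1)
    c(unname(fit$coefficients[2]), sqrt(s2 / sxx))
  }, numeric(2))
  slope <- slope_fit[1, ]
  slope_se <- slope_fit[2, ]
  is_jump <- abs(slope) >= params$slope_min & abs(slope) >= 2 * slope_se
  ev <- data.frame(curve_id = p$metadata$curve_id,
                   index = candidates$index,
                   separation_nm = p$separation[candidates$index],
                   step_height_nm = candidates$step_height_nm,
                   force_pN = candidates$step_force_pN,
                   class = ifelse(is_jump, "jump", "tether"),
                   loading_rate_pN_per_s = abs(slope) * v_nm_s,
                   pre_slope_pN_per_nm = slope,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$separation_nm), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("rupture_events", "data.frame")
  ev
}

#' Process one force curve end to end
#'
#' Composition of [correct_baseline()], [find_contact_point()],
#' [detect_steps()] and [classify_events()]: turns a raw force curve into a
#' corrected retract trace on a tip-sample separation axis plus a table of
#' classified rupture events sorted by separation.
#'
#' @param curve a [force_curve()]
#' @param params a [detection_params()]
#' @return list of class `scfs_detection` with elements `processed` (the
#'   `processed_curve`) and `events` (a `rupture_events` data frame)
#' @export
process_curve <- function(curve, params = detection_params()) {
  cid <- curve$metadata$curve_id
  withCallingHandlers({
    p <- correct_baseline(curve, params)
    p <- .add_separation(p)
    cand <- detect_steps(p, params)
    events <- classify_events(p, cand, params)
    structure(list(processed = p, events = events), class = "scfs_detection")
  }, error = function(e) {
    stop(sprintf("process_curve [%s]: %s", cid, conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.scfs_detection <- function(x, ...) {
  cat(sprintf("<scfs_detection> %s: %d events (%d jumps, %d tethers)\n",
              x$processed$metadata$curve_id, nrow(x$events),
              sum(x$events$class == "jump"), sum(x$events$class == "tether")))
  invisible(x)
}

#' Process every curve of a force map
#'
#' @param map a [force_map()]
#' @param params a [detection_params()]
#' @return list with `events` (row-bound `rupture_events`) and `qc` (per-curve
#'   data frame: `curve_id`, `baseline_sd_pN`, `contact_index`,
#'   `contact_flagged`, `n_events`, `n_jumps`)
#' @export
process_map <- function(map, params = detection_params()) {
  stopifnot(inherits(map, "force_map"))
  out <- lapply(map$curves, process_curve, params = params)
  events <- do.call(rbind, lapply(out, `[[`, "events"))
  qc <- do.call(rbind, lapply(out, function(o) {
    data.frame(curve_id = o$processed$metadata$curve_id,
               baseline_sd_pN = o$processed$baseline_sd,
               contact_index = o$processed$contact_index,
               contact_flagged = o$processed$contact_flagged,
               n_events = nrow(o$events),
               n_jumps = sum(o$events$class == "jump"),
               stringsAsFactors = FALSE)
  }))
  class(events) <- c("rupture_events", "data.frame")
  list(events = events, qc = qc)
}

#' Score detected events against ground truth
#'
#' Pairs detections with ground-truth events by nearest separation within a
#' tolerance (greedy, best matches first); unmatched truths are misses,
#' unmatched detections false positives.
#'
#' @param truth data frame with columns `curve_id`, `separation_nm`,
#'   `force_pN` (a simulator ground-truth table)
#' @param detected a `rupture_events` data frame
#' @param tol_nm matching tolerance on separation; by default twice the
#'   detection window expressed in nm via `velocity / sampling_rate`
#' @param params,metadata used only to derive the default `tol_nm`
#' @return list: `recall`, `precision`, `force_rmse_pN`, `n_truth`,
#'   `n_detected`, `n_matched`
#' @export
detection_benchmark <- function(truth, detected, tol_nm = NULL,
                                params = detection_params(),
                                metadata = curve_metadata()) {
  if (is.null(tol_nm))
    tol_nm <- 2 * params$window_w * .um_s_to_nm_s(metadata$velocity_v) /
      metadata$sampling_rate
  n_truth <- nrow(truth); n_det <- nrow(detected)
  if (n_det == 0 || n_truth == 0)
    return(list(recall = if (n_truth) 0 else NA_real_,
                precision = if (n_det) 0 else NA_real_,
                force_rmse_pN = NA_real_,
                n_truth = n_truth, n_detected = n_det, n_matched = 0L))
  pairs <- NULL
  for (cid in unique(truth$curve_id)) {
    ti <- which(truth$curve_id == cid)
    di <- which(detected$curve_id == cid)
    if (!length(di)) next
    dmat <- abs(outer(truth$separation_nm[ti], detected$separation_nm[di], "-"))
    cand <- which(dmat <= tol_nm, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    used_t <- logical(length(ti)); used_d <- logical(length(di))
    for (rr in seq_len(nrow(cand))) {
      a <- cand[rr, 1]; b <- cand[rr, 2]
      if (!used_t[a] && !used_d[b]) {
        used_t[a] <- used_d[b] <- TRUE
        pairs <- rbind(pairs, c(ti[a], di[b]))
      }
    }
  }
  n_match <- if (is.null(pairs)) 0L else nrow(pairs)
  rmse <- if (n_match)
    sqrt(mean((truth$force_pN[pairs[, 1]] - detected$force_pN[pairs[, 2]])^2))
  else NA_real_
  list(recall = n_match / n_truth,
       precision = n_match / n_det,
       force_rmse_pN = rmse,
       n_truth = n_truth, n_detected = n_det, n_matched = n_match)
}
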