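# Physics-based synthetic retract curves: independent single-bond ruptures
# (Bell-Evans under ramp loading through an effective stiffness k_eff),
# constant-force membrane-tether plateaus with exponential detach lengths,
# Gaussian deflection noise and linear baseline drift.  Each simulated curve
# carries its ground-truth event list so detection and statistics can be
# benchmarked without real data.

#' Generative model of cadherin-like bond ruptures
#'
#' Bonds engage sequentially at random separations and load through an
#' effective stiffness `k_eff` (cantilever and cell compliance in series, so
#' `k_eff` is well below the cantilever spring constant); each ruptures at a
#' force drawn from the Bell-Evans ramp-loading distribution at loading rate
#' `r = k_eff * v`.
#'
#' @param lambda mean number of bonds per curve (Poisson)
#' @param k0 unstressed off-rate, 1/s
#' @param x_beta distance to the transition state, nm
#' @param k_eff effective loading stiffness, pN/nm
#' @param anchor_range bonds engage at separations drawn uniformly from
#'   `[0, anchor_range]` nm
#' @return object of class `bond_model`
#' @export
bond_model <- function(lambda = 3, k0 = 0.5, x_beta = 0.3, k_eff = 0.2,
                       anchor_range = 1500) {
  stopifnot(lambda >= 0, k0 > 0, x_beta > 0, k_eff > 0, anchor_range > 0)
  structure(list(lambda = lambda, k0 = k0, x_beta = x_beta, k_eff = k_eff,
                 anchor_range = anchor_range), class = "bond_model")
}

#' Generative model of membrane tethers
#'
#' Tethers pull at a near-constant plateau force from the contact point until
#' an exponentially distributed detach length, then release in one step.
#'
#' @param lambda mean number of tethers per curve (Poisson)
#' @param plateau_force plateau force, pN
#' @param detach_scale mean detach length, nm (exponential)
#' @return object of class `tether_model`
#' @export
tether_model <- function(lambda = 1, plateau_force = 30, detach_scale = 500) {
  stopifnot(lambda >= 0, plateau_force > 0, detach_scale > 0)
  structure(list(lambda = lambda, plateau_force = plateau_force,
                 detach_scale = detach_scale), class = "tether_model")
}

#' Measurement-noise model
#'
#' @param deflection_sd white Gaussian deflection noise, nm
#' @param drift_slope linear baseline tilt, pN per nm of piezo travel
#' @return object of class `noise_model`
#' @export
noise_model <- function(deflection_sd = 0.1, drift_slope = 0.001) {
  stopifnot(deflection_sd >= 0)
  structure(list(deflection_sd = deflection_sd, drift_slope = drift_slope),
            class = "noise_model")
}

#' Full simulation configuration
#'
#' Bundles acquisition metadata and the generative models, plus the geometry
#' of the simulated cycle.  Identical configurations (same seed) produce
#' identical output.
#'
#' @param metadata [curve_metadata()]
#' @param bond [bond_model()]
#' @param tether [tether_model()]
#' @param noise [noise_model()]
#' @param seed integer RNG seed
#' @param retract_length_nm piezo travel of the retract segment, nm
#' @param contact_stiffness slope of the repulsive contact region, pN/nm
#' @param approach_free_nm off-contact approach travel before touching, nm
#' @param min_event_spacing_nm minimum separation between successive rupture /
#'   detach positions, and between the first event and the contact point;
#'   closer pairs are pushed apart (forces unchanged) so that generated
#'   events are resolvable at the detector's window scale
#' @return object of class `sim_config`
#' @export
sim_config <- function(metadata = curve_metadata(),
                       bond = bond_model(),
                       tether = tether_model(),
                       noise = noise_model(),
                       seed = 1L,
                       retract_length_nm = 10000,
                       contact_stiffness = 10,
                       approach_free_nm = 300,
                       min_event_spacing_nm = 60) {
  stopifnot(inherits(metadata, "curve_metadata"), inherits(bond, "bond_model"),
            inherits(tether, "tether_model"), inherits(noise, "noise_model"),
            retract_length_nm > 0, contact_stiffness > 0,
            min_event_spacing_nm >= 0)
  structure(list(metadata = metadata, bond = bond, tether = tether,
                 noise = noise, seed = as.integer(seed),
                 retract_length_nm = retract_length_nm,
                 contact_stiffness = contact_stiffness,
                 approach_free_nm = approach_free_nm,
                 min_event_spacing_nm = min_event_spacing_nm,
                 kbt = kBT(metadata$temperature)),
            class = "sim_config")
}

# push sorted event positions apart to a minimum spacing (left to right);
# forces are untouched, only positions (and bond anchors) shift.
.enforce_spacing <- function(pos, minsp) {
  if (length(pos) < 2 || minsp <= 0) return(pos)
  ord <- order(pos)
  p <- pos[ord]
  for (j in 2:length(p))
    if (p[j] < p[j - 1] + minsp) p[j] <- p[j - 1] + minsp
  pos[ord] <- p
  pos
}

#' Simulate one approach/dwell/retract force curve with ground truth
#'
#' The retract deflection trace is the sum of a repulsive contact-unloading
#' ramp, bond loading ramps each terminated by an instantaneous rupture step
#' at its sampled Bell-Evans force, constant tether plateaus terminated at
#' exponential detach lengths, linear baseline drift and white Gaussian
#' noise.  Approach and dwell are synthesized as a linear contact ramp to the
#' maximum load followed by a constant hold.  The returned ground truth lists
#' every event's retract sample index, separation, force (the realized trace
#' step) and class.
#'
#' @param config a [sim_config()]
#' @return list with elements `curve` (a [force_curve()]) and `truth` (data
#'   frame with columns `curve_id`, `index`, `separation_nm`, `force_pN`,
#'   `class`)
#' @export
simulate_retract_curve <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .simulate_retract_curve_impl(config)
}

.simulate_retract_curve_impl <- function(config) {
  m <- config$metadata
  k <- m$spring_constant_k
  v <- .um_s_to_nm_s(m$velocity_v)
  fs <- m$sampling_rate
  dt <- 1 / fs
  ds <- v * dt                               # piezo travel per sample, nm
  kbt <- config$kbt

  g0 <- m$max_load / config$contact_stiffness  # contact unload distance, nm
  L <- config$retract_length_nm
  n_ret <- max(2L, as.integer(round(L / ds)))
  g <- (seq_len(n_ret) - 1) * ds             # retract piezo travel
  s <- g - g0                                # nominal tip-sample separation

  # --- events -------------------------------------------------------------
  bm <- config$bond; tm <- config$tether
  n_b <- stats::rpois(1, bm$lambda)
  n_t <- stats::rpois(1, tm$lambda)
  anchors <- if (n_b) stats::runif(n_b, 0, bm$anchor_range) else numeric(0)
  r <- bm$k_eff * v
  f_bond <- if (n_b) sample_rupture_force(n_b, bm$k0, bm$x_beta, r, kbt) else numeric(0)
  pos_b <- anchors + f_bond / bm$k_eff       # rupture separations
  pos_t <- if (n_t) stats::rexp(n_t, rate = 1 / tm$detach_scale) else numeric(0)

  pos <- c(pos_b, pos_t)
  type <- rep(c("jump", "tether"), c(n_b, n_t))
  # the contact-unload edge at separation 0 acts as a spacing boundary too:
  # an event inside the unload ramp is not resolvable by a windowed detector
  shifted <- .enforce_spacing(c(0, pos), config$min_event_spacing_nm)[-1]
  anchors <- anchors + (shifted - pos)[seq_len(n_b)]   # keep bond force fixed
  pos <- shifted

  # --- retract force trace ------------------------------------------------
  f <- pmax(0, m$max_load - config$contact_stiffness * g)
  for (j in seq_len(n_b)) {
    act <- s >= anchors[j] & s < pos[j]
    f[act] <- f[act] - bm$k_eff * (s[act] - anchors[j])
  }
  for (j in seq_len(n_t)) {
    act <- s >= 0 & s < pos[n_b + j]
    f[act] <- f[act] - tm$plateau_force
  }

  # --- ground truth (events that fall inside the record) ------------------
  idx <- as.integer(ceiling((pos + g0) / ds)) + 1L   # first sample past the drop
  keep <- idx >= 2L & idx <= n_ret
  force_true <- c(if (n_b) bm$k_eff * (s[pmax(idx[seq_len(n_b)] - 1L, 1L)] - anchors),
                  rep(tm$plateau_force, n_t))
  truth <- data.frame(curve_id = rep(m$curve_id, sum(keep)),
                      index = idx[keep],
                      separation_nm = pos[keep],
                      force_pN = force_true[keep],
                      class = type[keep],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$index), , drop = FALSE]
  rownames(truth) <- NULL

  # --- assemble full cycle ------------------------------------------------
  nm <- config$noise
  n_app <- max(2L, as.integer(round((g0 + config$approach_free_nm) / ds)))
  n_dw <- as.integer(round(m$dwell_time * fs))
  z_max <- L
  z_contact <- z_max - g0
  z_app <- seq(z_max - g0 - config$approach_free_nm, z_max, length.out = n_app)
  f_app <- pmax(0, z_app - z_contact) * config$contact_stiffness
  z_ret <- z_max - g

  z <- c(z_app, rep(z_max, n_dw), z_ret)
  f_all <- c(f_app, rep(m$max_load, n_dw), f)
  n_tot <- length(z)
  defl <- f_all / k + c(rep(0, n_app + n_dw), nm$drift_slope * g / k)
  if (nm$deflection_sd > 0)
    defl <- defl + stats::rnorm(n_tot, 0, nm$deflection_sd)
  segment <- rep(c("approach", "dwell", "retract"), c(n_app, n_dw, n_ret))

  curve <- force_curve(time = (seq_len(n_tot) - 1) * dt,
                       z_position = z, deflection = defl,
                       segment = segment, metadata = m)
  list(curve = curve, truth = truth)
}

#' Simulate a force map (default 24 curves) with ground truth
#'
#' Child seeds are derived deterministically from the map seed and curve
#' index, so any single curve can be regenerated alone and matches the curve
#' produced within the full map.
#'
#' @param config a [sim_config()]; its seed is the map seed
#' @param n_curves curves per map (default 24)
#' @param map_id map identifier
#' @return list with elements `map` (a [force_map()]) and `truth` (row-bound
#'   per-curve ground truth)
#' @export
simulate_force_map <- function(config, n_curves = 24, map_id = "map1") {
  stopifnot(inherits(config, "sim_config"), n_curves >= 1)
  curves <- vector("list", n_curves)
  truths <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    ci <- config
    ci$seed <- .child_seed(config$seed, map_id, i)
    ci$metadata$curve_id <- sprintf("%s_c%02d", map_id, i)
    out <- simulate_retract_curve(ci)
    curves[[i]] <- out$curve
    truths[[i]] <- out$truth
  }
  list(map = force_map(curves, map_id = map_id),
       truth = do.call(rbind, truths))
}
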