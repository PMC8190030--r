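# Bell-Evans rupture-force distribution under a linear force ramp.
#
# A single bond loaded at constant rate r (pN/s) with force-dependent
# off-rate k(F) = k0 * exp(F * x_beta / kBT) survives to force F with
# probability
#   S(F) = exp( (k0 * kBT / (x_beta * r)) * (1 - exp(F * x_beta / kBT)) ),
# giving the closed-form quantile used for inverse-CDF sampling and the
# most probable rupture force F* = (kBT/x_beta) * log(r x_beta / (k0 kBT)).

#' Bell-Evans rupture-force distribution
#'
#' Distribution of the first-rupture force of a single bond under a linear
#' force ramp `F(t) = r t`, with unstressed off-rate `k0` and distance to the
#' transition state `x_beta`.
#'
#' `pbell` is the CDF, `qbell` the quantile function,
#' `bell_mode` the most probable rupture force
#' `(kBT/x_beta) log(r x_beta / (k0 kBT))` (returned as 0 when the argument
#' of the log is below 1, i.e. in the near-equilibrium regime), and
#' `bell_median` the closed-form median.
#'
#' @param f force, pN
#' @param p probability in (0, 1)
#' @param k0 unstressed off-rate, 1/s (> 0)
#' @param x_beta distance to the transition state, nm (> 0)
#' @param r loading rate, pN/s (> 0)
#' @param kbt thermal energy, pN nm
#' @return numeric vector
#' @examples
#' bell_mode(k0 = 0.5, x_beta = 0.3, r = 600, kbt = 4.281)  # ~63.2 pN
#' @export
pbell <- function(f, k0, x_beta, r, kbt = kBT()) {
  .check_bell(k0, x_beta, r, kbt)
  ifelse(f <= 0, 0,
         1 - exp((k0 * kbt / (x_beta * r)) * (1 - exp(f * x_beta / kbt))))
}

#' @rdname pbell
#' @export
qbell <- function(p, k0, x_beta, r, kbt = kBT()) {
  .check_bell(k0, x_beta, r, kbt)
  stopifnot(all(p >= 0 & p < 1))
  (kbt / x_beta) * log1p(-(x_beta * r / (k0 * kbt)) * log1p(-p))
}

#' @rdname pbell
#' @export
bell_mode <- function(k0, x_beta, r, kbt = kBT()) {
  .check_bell(k0, x_beta, r, kbt)
  arg <- r * x_beta / (k0 * kbt)
  ifelse(arg <= 1, 0, (kbt / x_beta) * log(arg))
}

#' @rdname pbell
#' @export
bell_median <- function(k0, x_beta, r, kbt = kBT()) {
  qbell(0.5, k0, x_beta, r, kbt)
}

.check_bell <- function(k0, x_beta, r, kbt) {
  if (any(r <= 0)) stop("Bell-Evans: loading rate r must be > 0")
  stopifnot(all(k0 > 0), all(x_beta > 0), all(kbt > 0))
}

#' Sample rupture forces by inverse-CDF
#'
#' Draws rupture forces from the Bell-Evans ramp-loading distribution by
#' transforming uniforms: `F = (kBT/x_beta) log(1 - (x_beta r / (k0 kBT)) log u)`
#' with `u ~ U(0,1)` playing the survival probability (so `u -> 1` gives
#' `F -> 0`).
#'
#' @param n number of draws (ignored when `u` is supplied)
#' @param k0,x_beta,r,kbt see [pbell()]
#' @param u optional uniforms in (0, 1) to transform deterministically
#' @return rupture forces, pN
#' @export
sample_rupture_force <- function(n, k0, x_beta, r, kbt = kBT(), u = NULL) {
  .check_bell(k0, x_beta, r, kbt)
  if (is.null(u)) u <- stats::runif(n)
  stopifnot(all(u > 0 & u < 1))
  (kbt / x_beta) * log1p(-(x_beta * r / (k0 * kbt)) * log(u))
}

#' Solve the Bell off-rate that yields a target median rupture force
#'
#' Inverts the closed-form median of the ramp-loading Bell-Evans
#' distribution: given a target median `f_median` at loading rate `r`,
#' returns `k0 = x_beta r log(2) / (kBT (exp(f_median x_beta / kBT) - 1))`.
#' Used by the condition presets to pin the simulated force scale to a
#' reference median at the calibration velocity.
#'
#' @param f_median target median rupture force, pN (> 0)
#' @param x_beta,r,kbt see [pbell()]
#' @return off-rate `k0`, 1/s
#' @export
bell_k0_for_median <- function(f_median, x_beta, r, kbt = kBT()) {
  stopifnot(f_median > 0, x_beta > 0, r > 0, kbt > 0)
  x_beta * r * log(2) / (kbt * expm1(f_median * x_beta / kbt))
}
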