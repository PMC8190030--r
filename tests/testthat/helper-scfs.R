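# Shared helpers for the test suite.

# A minimal retract-only force curve from a deflection trace (nm).  The piezo
# retracts at ds nm/sample; metadata defaults unless overridden.
make_retract_curve <- function(deflection, ds = 1.5, fs = 2000, meta = NULL) {
  n <- length(deflection)
  if (is.null(meta)) meta <- curve_metadata(curve_id = "testcurve")
  z <- seq(n * ds, ds, by = -ds)
  force_curve(time = (seq_len(n) - 1) / fs, z_position = z,
              deflection = deflection,
              segment = rep("retract", n), metadata = meta)
}

# Kolmogorov-Smirnov sup distance between a sample and an analytic CDF.
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  u <- cdf(x)
  max(abs(seq_len(n) / n - u), abs((seq_len(n) - 1) / n - u))
}

# Independent brute-force two-sided rank-sum p-value: enumerate every
# assignment of the pooled observations to group a and count Mann-Whitney U
# (ties count 1/2).  Written from the U-statistic definition, not shared with
# the package implementation.
bruteforce_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a); N <- length(pooled)
  u_of <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n_a))
  us <- apply(utils::combn(N, n_a), 2, u_of)
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# The exact finite-difference discontinuity scan used as detection oracle on
# noise-free curves: indices where the retract force steps up by more than
# `thresh` pN between adjacent samples.  The trace is piecewise linear with
# non-positive slopes away from events, so any up-step is a discontinuity and
# the threshold only needs to clear floating-point granularity.
oracle_step_scan <- function(curve, thresh = 1e-3) {
  ret <- curve$segment == "retract"
  force <- curve$metadata$spring_constant_k * curve$deflection[ret]
  which(diff(force) > thresh) + 1L
}
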