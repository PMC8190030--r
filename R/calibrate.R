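# Thermal-tune spring-constant calibration: the force-scale anchor of the
# pipeline.  Two routes: (i) equipartition on the detrended deflection
# variance, (ii) a Welch-averaged power spectrum fitted to the SHO line shape
# plus a white floor, integrated analytically.  Deflection is assumed already
# expressed in nm (no optical-lever sensitivity stage).

#' Spring constant by equipartition
#'
#' Removes mean and linear trend from a thermal deflection record and
#' estimates the spring constant as `k = kBT / var(deflection)`.  The
#' confidence interval treats the variance as chi-square distributed at the
#' record's effective sample size, computed from the integrated
#' autocorrelation time (thermal records are correlated at the resonance
#' time scale, so the nominal sample count overstates the information).
#'
#' @param rec a `thermal_record` (see [thermal_record()])
#' @param mode_correction optional multiplicative correction for the first
#'   flexural mode shape (commonly ~1.09 in thermal tuning); default 1, i.e.
#'   no correction
#' @param conf confidence level for the interval
#' @return list of class `k_estimate`: `k` (pN/nm), `ci_low`, `ci_high`,
#'   `n_eff`, `method = "equipartition"`
#' @export
estimate_k_equipartition <- function(rec, mode_correction = 1, conf = 0.95) {
  stopifnot(inherits(rec, "thermal_record"))
  x <- rec$deflection
  n <- length(x)
  if (n < 1e4)
    stop("estimate_k_equipartition: need at least 1e4 samples")
  tt <- seq_along(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  v <- sum(x^2) / (n - 2)
  if (v <= 0 || !is.finite(v) || v < .Machine$double.eps)
    stop("estimate_k_equipartition: degenerate record (zero variance)")
  kbt <- kBT(rec$temperature)
  k_hat <- mode_correction * kbt / v

  # effective sample size from the integrated autocorrelation time
  max_lag <- min(n - 1, 10000)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = FALSE)$acf[-1]
  first_neg <- which(ac <= 0)[1]
  tau <- 1 + 2 * sum(ac[seq_len(if (is.na(first_neg)) max_lag else first_neg - 1)])
  n_eff <- max(4, n / max(tau, 1))
  alpha <- 1 - conf
  v_lo <- v * n_eff / stats::qchisq(1 - alpha / 2, n_eff)
  v_hi <- v * n_eff / stats::qchisq(alpha / 2, n_eff)
  structure(list(k = k_hat,
                 ci_low = mode_correction * kbt / v_hi,
                 ci_high = mode_correction * kbt / v_lo,
                 n_eff = n_eff, variance = v,
                 method = "equipartition"),
            class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("<k_estimate> k = %.3f pN/nm (CI %.3f-%.3f), method: %s\n",
              x$k, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

# Welch-averaged one-sided PSD (Hann window, 50% overlap), nm^2/Hz
.welch_psd <- function(x, fs, n_segments = 50) {
  n <- length(x)
  seg_len <- 2^floor(log2(2 * n / (n_segments + 1)))
  seg_len <- max(64, min(seg_len, n))
  step <- seg_len %/% 2
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  u <- sum(w^2)
  half <- seg_len %/% 2
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / (fs * u)
    acc <- acc + 2 * p[2:(half + 1)]          # one-sided, DC dropped
  }
  list(freq = (1:half) * fs / seg_len,
       psd = acc / length(starts),
       n_avg = length(starts))
}

#' Spring constant from an SHO fit to the thermal spectrum
#'
#' Computes a Welch-averaged power spectrum of the (detrended) record and
#' fits the simple-harmonic-oscillator line shape plus a white floor,
#' `P(f) = A f0^4 / ((f^2 - f0^2)^2 + (f f0 / Q)^2) + B`.  The spring
#' constant follows from equipartition applied to the integrated SHO
#' component, `var = pi A f0 Q / 2`, so `k = kBT / var`.  A record without a
#' resonance peak (white noise only) is rejected before fitting.
#'
#' @param rec a `thermal_record`
#' @param mode_correction as in [estimate_k_equipartition()]
#' @param min_averages minimum number of spectral averages required
#' @return list of class `sho_fit`: `k` (pN/nm), `f0` (Hz), `Q`, `A`, `B`,
#'   `psd` (the averaged spectrum), `method = "sho_psd"`
#' @export
fit_sho_psd <- function(rec, mode_correction = 1, min_averages = 50) {
  stopifnot(inherits(rec, "thermal_record"))
  x <- rec$deflection
  tt <- seq_along(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  W <- .welch_psd(x, rec$fs, n_segments = min_averages)
  if (W$n_avg < min_averages)
    stop("fit_sho_psd: record too short for the requested spectral averages")
  f <- W$freq; p <- W$psd

  peak_i <- which.max(p)
  if (p[peak_i] / stats::median(p) < 10 || peak_i <= 2 || peak_i >= length(p) - 2)
    stop("fit_sho_psd: no resonance peak in the spectrum (model mismatch)")
  f0_init <- f[peak_i]
  B_init <- stats::median(p[f > 1.5 * f0_init])
  if (!is.finite(B_init) || B_init <= 0) B_init <- min(p[p > 0])
  # half-power width -> Q
  above <- which(p > p[peak_i] / 2)
  width <- max(f[above[above >= peak_i - 50 & above <= peak_i + 50]]) -
    min(f[above[above >= peak_i - 50 & above <= peak_i + 50]])
  Q_init <- max(0.7, f0_init / max(width, f[2] - f[1]))
  A_init <- p[peak_i] / Q_init^2

  fit <- tryCatch(
    minpack.lm::nlsLM(
      log(p) ~ log(A * f0^4 / ((f^2 - f0^2)^2 + (f * f0 / Q)^2) + B),
      start = list(A = A_init, f0 = f0_init, Q = Q_init, B = B_init),
      lower = c(A = 0, f0 = f[2], Q = 0.1, B = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_sho_psd: SHO fit did not converge: ", conditionMessage(e)))
  cf <- as.list(stats::coef(fit))
  if (cf$f0 <= 0 || cf$Q <= 0 || cf$A <= 0)
    stop("fit_sho_psd: SHO fit converged to a non-physical optimum")
  sho_var <- pi * cf$A * cf$f0 * cf$Q / 2      # integral of the SHO term
  kbt <- kBT(rec$temperature)
  structure(list(k = mode_correction * kbt / sho_var,
                 f0 = cf$f0, Q = cf$Q, A = cf$A, B = cf$B,
                 psd = W, method = "sho_psd"),
            class = "sho_fit")
}

#' @export
print.sho_fit <- function(x, ...) {
  cat(sprintf("<sho_fit> k = %.3f pN/nm, f0 = %.1f Hz, Q = %.2f\n",
              x$k, x$f0, x$Q))
  invisible(x)
}
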