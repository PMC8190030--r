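# Thermally driven cantilever deflection: a stationary Gaussian series with a
# simple-harmonic-oscillator (SHO) spectrum, synthesized in the frequency
# domain with the one-sided PSD normalized so the expected variance equals
# kBT/k (equipartition).

# one-sided SHO line shape (unnormalized): f0^4 / ((f^2-f0^2)^2 + (f f0/Q)^2)
.sho_shape <- function(f, f0, Q) {
  f0^4 / ((f^2 - f0^2)^2 + (f * f0 / Q)^2)
}

#' Simulate a thermal deflection record
#'
#' Generates a stationary Gaussian deflection time series whose one-sided
#' power spectral density follows the simple-harmonic-oscillator line shape
#' with resonance `f0` and quality factor `Q`, normalized so that the
#' expected variance equals `kBT / k` (equipartition).  Synthesis is by
#' Fourier-domain colouring of complex Gaussian noise.
#'
#' @param k spring constant, pN/nm (> 0)
#' @param kbt thermal energy, pN nm
#' @param f0 resonance frequency, Hz
#' @param Q quality factor (dimensionless)
#' @param fs sampling rate, Hz; must exceed `2 * f0`
#' @param duration record length, s
#' @param seed RNG seed
#' @return object of class `thermal_record`: list with `deflection` (nm),
#'   `fs` (Hz) and `temperature` (K, back-computed from `kbt`)
#' @examples
#' rec <- simulate_thermal_deflection(k = 60, duration = 5, seed = 1)
#' var(rec$deflection) * 60 / kBT()  # ~1 (equipartition)
#' @export
simulate_thermal_deflection <- function(k, kbt = kBT(), f0 = 2000, Q = 3,
                                        fs = 20000, duration = 1, seed = 1L) {
  stopifnot(k > 0, kbt > 0, f0 > 0, Q > 0, fs > 0, duration > 0)
  if (fs <= 2 * f0)
    stop("simulate_thermal_deflection: fs must exceed twice the resonance f0")
  set.seed(as.integer(seed))
  n <- as.integer(round(fs * duration))
  if (n < 8) stop("simulate_thermal_deflection: record too short")
  df <- fs / n
  half <- n %/% 2
  fpos <- (1:half) * df
  S <- .sho_shape(fpos, f0, Q)
  S <- S * (kbt / k) / (sum(S) * df)            # normalize variance to kBT/k

  # hermitian spectrum -> real series; bin k gets E|Z_k|^2 = n^2 S_k df / 2
  amp <- n * sqrt(S * df / 4)
  Z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * amp
  if (n %% 2 == 0)           # real Nyquist bin carries a full (unpaired) share
    Z[half] <- complex(real = stats::rnorm(1), imaginary = 0) *
      n * sqrt(S[half] * df / 2) * sqrt(2)
  spec <- complex(length.out = n)
  spec[2:(half + 1)] <- Z
  spec[n:(n - half + 2)] <- Conj(Z[seq_len(half - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  structure(list(deflection = x, fs = fs, temperature = kbt / kB_pN_nm),
            class = "thermal_record")
}

#' Construct a thermal record from an existing deflection series
#'
#' @param deflection deflection samples, nm
#' @param fs sampling rate, Hz
#' @param temperature temperature, K
#' @return object of class `thermal_record`
#' @export
thermal_record <- function(deflection, fs, temperature = 310.15) {
  stopifnot(is.numeric(deflection), fs > 0, temperature > 0)
  structure(list(deflection = as.numeric(deflection), fs = fs,
                 temperature = temperature),
            class = "thermal_record")
}
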