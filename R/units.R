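# Internal unit system: force pN, length nm, time s, velocity um/s at the user
# surface (converted to nm/s internally), frequency Hz, temperature K.
# Conversions happen only at I/O boundaries.

#' Boltzmann constant in pN nm / K
#'
#' `1.380649e-23` J/K expressed in the package's internal unit system
#' (1 J = 1e21 pN nm).
#' @export
kB_pN_nm <- 1.380649e-2

#' Thermal energy at a given temperature
#'
#' @param temperature_K temperature in kelvin (default 310.15 K, i.e. 37 C,
#'   the physiological temperature at which live-cell AFM measurements are run).
#' @return thermal energy kBT in pN nm (about 4.28 pN nm at 310.15 K).
#' @examples
#' kBT(310.15)
#' @export
kBT <- function(temperature_K = 310.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  kB_pN_nm * temperature_K
}

# um/s -> nm/s
.um_s_to_nm_s <- function(v) v * 1000

# deterministic child-seed derivation: fold strings/integers into a 31-bit
# integer stream seed.  Pure double arithmetic below 2^53, so stable across
# platforms.
.child_seed <- function(seed, ...) {
  parts <- list(...)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.numeric(p) + 11) %% 2147483647
  }
  as.integer(h)
}
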