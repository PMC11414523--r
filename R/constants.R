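# Physical constants used throughout. Fixed values so that printed-value
# regression tests are reproducible bit-for-bit across platforms.

#' Physical constants
#'
#' Vacuum permittivity (F/m), vacuum permeability (H/m), speed of light
#' (m/s) and the gyromagnetic ratio of the proton divided by 2*pi
#' (Hz/T) as used by all wavenumber computations in this package.
#'
#' @format A named list with elements `eps0`, `mu0`, `c0`,
#'   `gamma_over_2pi`.
#' @export
leadheat_constants <- list(
  eps0 = 8.8541878128e-12,
  mu0  = 4e-7 * pi,
  c0   = 1 / sqrt(8.8541878128e-12 * 4e-7 * pi),
  gamma_over_2pi = 42.58e6
)

#' Larmor frequency for a given static field strength
#'
#' Proton resonance frequency `f = (gamma/2*pi) * B0` with the
#' conventional rounded constant 42.58 MHz/T. All model functions also
#' accept an explicit frequency, so this helper is a convenience only.
#'
#' @param field_strength_T Static magnetic field strength in tesla
#'   (positive scalar), e.g. 1.5 or 3.
#' @param gamma_over_2pi Gyromagnetic ratio over 2*pi in Hz/T.
#' @return Frequency in Hz.
#' @examples
#' larmor_frequency(1.5)  # 63.87 MHz
#' larmor_frequency(3.0)  # 127.74 MHz
#' @export
larmor_frequency <- function(field_strength_T,
                             gamma_over_2pi = leadheat_constants$gamma_over_2pi) {
  if (!is.numeric(field_strength_T) || any(!is.finite(field_strength_T)) ||
      any(field_strength_T <= 0)) {
    stop("`field_strength_T` must be a positive, finite number", call. = FALSE)
  }
  gamma_over_2pi * field_strength_T
}
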