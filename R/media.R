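# Complex wavenumbers: lossy embedding medium, lossless insulator, and
# the insulated-conductor (King) wavenumber from insulated antenna theory.
#
# Sign convention, used everywhere in this package: kR >= 0 (so that the
# wavelength lambda = 2*pi/kR is positive) and kI <= 0 (so that the
# transfer function e^{-ikl} decays, i.e. the imaginary part produces
# losses rather than unbounded gain). King's original derivation uses
# the opposite sign for the imaginary part, so the embedding-medium
# wavenumber is conjugated before entering the Hankel-function argument
# and the result is mapped back into this package's convention.

#' Electromagnetic material properties
#'
#' Describes a homogeneous medium by its relative permittivity,
#' conductivity and relative permeability. Tissue, phantom gel, water
#' and wire insulation are all represented this way; for MR applications
#' the permeability is that of free space.
#'
#' @param relative_permittivity Dimensionless relative permittivity
#'   (> 0), e.g. 80 for ASTM phantom gel.
#' @param conductivity Conductivity in S/m (>= 0), e.g. 0.47 for ASTM
#'   gel; 0 for an ideal insulator.
#' @param relative_permeability Dimensionless relative permeability
#'   (> 0); default 1.
#' @return An object of class `material_properties`.
#' @examples
#' astm_gel <- material_properties(80, 0.47)
#' @export
material_properties <- function(relative_permittivity, conductivity,
                                relative_permeability = 1) {
  stopifnot(is.numeric(relative_permittivity), length(relative_permittivity) == 1,
            is.numeric(conductivity), length(conductivity) == 1,
            is.numeric(relative_permeability), length(relative_permeability) == 1)
  if (!is.finite(relative_permittivity) || relative_permittivity <= 0)
    stop("`relative_permittivity` must be > 0", call. = FALSE)
  if (!is.finite(conductivity) || conductivity < 0)
    stop("`conductivity` must be >= 0", call. = FALSE)
  if (!is.finite(relative_permeability) || relative_permeability <= 0)
    stop("`relative_permeability` must be > 0", call. = FALSE)
  structure(list(relative_permittivity = relative_permittivity,
                 conductivity = conductivity,
                 relative_permeability = relative_permeability),
            class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("<material_properties> eps_r = %g, sigma = %g S/m, mu_r = %g\n",
              x$relative_permittivity, x$conductivity, x$relative_permeability))
  invisible(x)
}

#' Complex wavenumber with enforced loss convention
#'
#' A complex spatial frequency `k = kR + i kI` in rad/m with `kR >= 0`
#' and `kI <= 0`. The real part sets the wavelength in the conductor or
#' medium (`lambda = 2*pi/kR`), the imaginary part the attenuation.
#'
#' @param kR Real part, rad/m, must be >= 0.
#' @param kI Imaginary part, rad/m, must be <= 0.
#' @return An object of class `wavenumber`.
#' @seealso [wavelength()], [loss_ratio()], [as.complex.wavenumber()]
#' @export
wavenumber <- function(kR, kI = 0) {
  stopifnot(is.numeric(kR), length(kR) == 1, is.numeric(kI), length(kI) == 1)
  if (!is.finite(kR) || kR < 0) stop("`kR` must be finite and >= 0", call. = FALSE)
  if (!is.finite(kI) || kI > 0) stop("`kI` must be finite and <= 0", call. = FALSE)
  structure(list(kR = kR, kI = kI), class = "wavenumber")
}

# Map an arbitrary complex square root onto the package convention:
# principal branch with Re >= 0, then force the imaginary part negative.
.as_convention <- function(k) {
  if (Re(k) < 0) k <- -k
  wavenumber(Re(k), -abs(Im(k)))
}

#' @export
print.wavenumber <- function(x, ...) {
  cat(sprintf("<wavenumber> (%.4f %+.4fi) rad/m  [u = %.4f, lambda = %.4f m]\n",
              x$kR, x$kI, loss_ratio(x), wavelength(x)))
  invisible(x)
}

#' @rdname wavenumber
#' @param x A `wavenumber` object.
#' @param ... Unused.
#' @export
as.complex.wavenumber <- function(x, ...) complex(real = x$kR, imaginary = x$kI)

#' Wavelength associated with a wavenumber
#'
#' `lambda = 2*pi/kR` in metres.
#'
#' @param k A [wavenumber()].
#' @return Wavelength in m (`Inf` when `kR = 0`).
#' @export
wavelength <- function(k) {
  stopifnot(inherits(k, "wavenumber"))
  if (k$kR == 0) return(Inf)
  2 * pi / k$kR
}

#' Dimensionless loss ratio of a wavenumber
#'
#' `u = -kI/kR`, the attenuation per radian of phase. Controls where the
#' resonant length falls between a quarter and half wavelength.
#'
#' @param k A [wavenumber()].
#' @return Non-negative dimensionless scalar (`NaN` when `kR = 0` and
#'   `kI = 0`).
#' @export
loss_ratio <- function(k) {
  stopifnot(inherits(k, "wavenumber"))
  if (k$kR == 0 && k$kI == 0) return(NaN)
  -k$kI / k$kR
}

#' Insulated-wire cross-section geometry
#'
#' Conductor radius `a`, insulation outer radius `b` (both metres) and
#' the insulation's relative permittivity.
#'
#' @param conductor_radius_a Conductor radius in m, > 0.
#' @param insulation_outer_radius_b Insulation outer radius in m, > a.
#' @param insulation_relative_permittivity Relative permittivity of the
#'   insulation, >= 1.
#' @return An object of class `wire_geometry`.
#' @examples
#' wire_geometry(0.390e-3, 0.625e-3, 2.3)
#' @export
wire_geometry <- function(conductor_radius_a, insulation_outer_radius_b,
                          insulation_relative_permittivity) {
  stopifnot(is.numeric(conductor_radius_a), is.numeric(insulation_outer_radius_b),
            is.numeric(insulation_relative_permittivity))
  if (!(conductor_radius_a > 0))
    stop("`conductor_radius_a` must be > 0", call. = FALSE)
  if (!(insulation_outer_radius_b > conductor_radius_a))
    stop("`insulation_outer_radius_b` must exceed `conductor_radius_a`",
         call. = FALSE)
  if (!(insulation_relative_permittivity >= 1))
    stop("`insulation_relative_permittivity` must be >= 1", call. = FALSE)
  structure(list(conductor_radius_a = conductor_radius_a,
                 insulation_outer_radius_b = insulation_outer_radius_b,
                 insulation_relative_permittivity = insulation_relative_permittivity),
            class = "wire_geometry")
}

#' @export
print.wire_geometry <- function(x, ...) {
  cat(sprintf("<wire_geometry> a = %.3f mm, b = %.3f mm, eps_i = %g\n",
              1e3 * x$conductor_radius_a, 1e3 * x$insulation_outer_radius_b,
              x$insulation_relative_permittivity))
  invisible(x)
}

#' Complex wavenumber of a lossy medium
#'
#' Standard electromagnetic wavenumber of a homogeneous conductive
#' dielectric, `k = omega * sqrt(mu * (eps + i sigma/omega))`, returned
#' in the package convention (`kR >= 0`, `kI <= 0`).
#'
#' @param props A [material_properties()].
#' @param frequency Frequency in Hz, > 0.
#' @return A [wavenumber()].
#' @examples
#' medium_wavenumber(material_properties(80, 0.47), larmor_frequency(3))
#' @export
medium_wavenumber <- function(props, frequency) {
  stopifnot(inherits(props, "material_properties"))
  if (!is.numeric(frequency) || length(frequency) != 1 || frequency <= 0)
    stop("`frequency` must be a positive scalar in Hz", call. = FALSE)
  w <- 2 * pi * frequency
  eps <- props$relative_permittivity * leadheat_constants$eps0
  mu  <- props$relative_permeability * leadheat_constants$mu0
  if (props$conductivity == 0) {
    # lossless limit: purely real, no branch ambiguity
    return(wavenumber(w * sqrt(eps * mu), 0))
  }
  k <- w * sqrt(mu * complex(real = eps, imaginary = props$conductivity / w))
  .as_convention(k)
}

#' Real wavenumber of a lossless insulator
#'
#' `ki = omega * sqrt(eps * mu)` with zero conductivity; the imaginary
#' part is exactly zero.
#'
#' @param relative_permittivity Relative permittivity, >= 1.
#' @param frequency Frequency in Hz, > 0.
#' @return A [wavenumber()] with `kI = 0`.
#' @examples
#' insulator_wavenumber(2.3, larmor_frequency(3))
#' @export
insulator_wavenumber <- function(relative_permittivity, frequency) {
  if (!is.numeric(relative_permittivity) || relative_permittivity < 1)
    stop("`relative_permittivity` must be >= 1", call. = FALSE)
  medium_wavenumber(material_properties(relative_permittivity, 0), frequency)
}

#' King wavenumber of an insulated conductor in a conductive medium
#'
#' Insulated antenna theory gives the wavenumber of current propagation
#' along an insulated wire embedded in a conductive medium as
#' `k = ki * sqrt(1 + F(kt*b) / ln(b/a))` with
#' `F(z) = H0(z) / (z * H1(z))`, where `H0`, `H1` are Hankel functions
#' of the first kind, `ki` the (real) insulator wavenumber, `kt` the
#' complex wavenumber of the embedding medium and `a`, `b` the conductor
#' and insulation radii. The Hankel argument is evaluated with the
#' opposite sign convention for the imaginary part (King's choice,
#' `Im >= 0`), i.e. `kt` is conjugated on entry; the result is
#' re-expressed with `kR >= 0`, `kI <= 0`.
#'
#' The theory assumes a conductive embedding medium; a lossless medium
#' (`kt` real) is evaluated anyway with a warning.
#'
#' @param insulator_k Insulator [wavenumber()] (real, `kI = 0`).
#' @param medium_k Embedding-medium [wavenumber()].
#' @param geometry A [wire_geometry()].
#' @return A [wavenumber()].
#' @examples
#' f <- larmor_frequency(3)
#' kt <- medium_wavenumber(material_properties(80, 0.47), f)
#' ki <- insulator_wavenumber(2.3, f)
#' king_wavenumber(ki, kt, wire_geometry(0.390e-3, 0.625e-3, 2.3))
#' @export
king_wavenumber <- function(insulator_k, medium_k, geometry) {
  stopifnot(inherits(insulator_k, "wavenumber"), inherits(medium_k, "wavenumber"),
            inherits(geometry, "wire_geometry"))
  if (medium_k$kI == 0) {
    warning("insulated antenna theory assumes a conductive embedding medium; ",
            "the supplied medium wavenumber is purely real", call. = FALSE)
  }
  a <- geometry$conductor_radius_a
  b <- geometry$insulation_outer_radius_b
  # King's sign convention for the embedding medium: Im(kt) >= 0
  z <- Conj(as.complex(medium_k)) * b
  h1 <- hankel_h1(1, z)
  if (Mod(h1) < 1e-300)
    stop("H1(kt*b) vanishes at the evaluated argument; ",
         "the insulated-antenna expression is singular here", call. = FALSE)
  f_z <- hankel_h1(0, z) / (z * h1)
  k <- as.complex(insulator_k) * sqrt(1 + f_z / log(b / a))
  .as_convention(k)
}
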