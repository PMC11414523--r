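# Resonant lead length: the length maximising the lead-tip temperature
# rise. For the simple exponential model and for the transmission line
# model with an electrically open end (gamma = 1), setting the derivative
# of the closed-form dT(d) to zero reduces the maximisation to a
# transcendental equation in the dimensionless variables
#   u = -kI/kR   (loss per radian of phase)
#   g = kR*d/pi  (length in units of half wavelengths),
# whose smallest positive root lies in [1/2, 1]: the resonant length is
# bounded between a quarter and half wavelength in the conductor.

G_ROOT_TOL <- 1e-13
U_INFINITE <- 1e6

.check_u <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u) & u != Inf) || any(u < 0))
    stop("`u` must be >= 0", call. = FALSE)
}

#' Resonance root g(u) of the simple exponential model
#'
#' Smallest positive root of
#' `-u e^{-pi u g} + u cos(pi g) + sin(pi g) = 0`, the stationarity
#' condition of the closed-form temperature rise. `g(0) = 1` exactly
#' (half-wavelength resonance) and `g` decreases monotonically to 1/2 as
#' `u` grows (quarter-wavelength limit).
#'
#' @param u Loss ratio(s) `-kI/kR`, >= 0 (vectorised).
#' @return Root(s) in `[0.5, 1]`.
#' @examples
#' g_sem(c(0, 0.1, 5))
#' @export
g_sem <- function(u) {
  .check_u(u)
  vapply(u, function(ui) {
    if (ui == 0) return(1)
    if (ui > U_INFINITE) return(0.5)
    f <- function(g) -ui * exp(-pi * ui * g) + ui * cospi(g) + sinpi(g)
    stats::uniroot(f, c(0.5 + 1e-12, 1), tol = G_ROOT_TOL)$root
  }, numeric(1))
}

#' Resonance root g(u) of the open-ended transmission line model
#'
#' Smallest positive root of `kR tan(kR d) + kI tanh(kI d) = 0` (the
#' gamma = 1 stationarity condition) expressed as `g = kR d / pi`, i.e.
#' the root of `tan(pi g) + u tanh(pi u g) = 0` in `(1/2, 1]`. The
#' tangent argument lies in the second quadrant, so the resonant length
#' is again bounded between a quarter and half wavelength.
#'
#' @inheritParams g_sem
#' @return Root(s) in `[0.5, 1]`.
#' @examples
#' g_tlm_open(c(0, 0.5, 1))
#' @export
g_tlm_open <- function(u) {
  .check_u(u)
  vapply(u, function(ui) {
    if (ui == 0) return(1)
    if (ui > U_INFINITE) return(0.5)
    f <- function(g) tanpi(g) + ui * tanh(pi * ui * g)
    # tan(pi g) -> -Inf as g -> 1/2+, f(1) = u tanh(pi u) > 0
    stats::uniroot(f, c(0.5 + 1e-9, 1), tol = G_ROOT_TOL)$root
  }, numeric(1))
}

#' Resonant lead length of a transfer model
#'
#' The lead length maximising the constant-field temperature rise. For
#' the SEM and the TLM with `gamma = 1` the analytic reduction
#' `d_res = (lambda/2) g(u)` is used; for other reflection coefficients
#' the closed-form temperature rise is maximised numerically (coarse
#' grid plus golden-section refinement). `gamma = 0` reduces exactly to
#' the SEM result.
#'
#' @param model A [transfer_model()]. The wavenumber must have
#'   `kR > 0`.
#' @param search_max Upper end of the search interval in m for the
#'   numerical branch; defaults to one wavelength.
#' @param grid_step Coarse grid step in m for the numerical branch
#'   (default 0.5 mm).
#' @return Resonant length in m.
#' @examples
#' k <- wavenumber(6.7454, -0.6840)
#' resonant_length(transfer_model("sem", k))            # ~0.44 m at 1.5 T
#' resonant_length(transfer_model("tlm", k, gamma = 1))
#' @export
resonant_length <- function(model, search_max = NULL, grid_step = 5e-4) {
  stopifnot(inherits(model, "transfer_model"))
  k <- model$k
  if (k$kR <= 0)
    stop("resonant length is undefined for kR = 0 ",
         "(temperature rise grows monotonically with length)", call. = FALSE)
  u <- loss_ratio(k)
  lam <- wavelength(k)
  if (model$kind == "sem") return(lam / 2 * g_sem(u))
  g <- model$gamma
  if (is.complex(g) && Im(g) == 0) g <- Re(g)
  if (identical(g, 0)) return(lam / 2 * g_sem(u))
  if (identical(g, 1)) return(lam / 2 * g_tlm_open(u))
  if (is.null(search_max)) search_max <- lam
  if (!is.numeric(search_max) || search_max <= grid_step)
    stop("invalid search range", call. = FALSE)
  dd <- seq(grid_step, search_max, by = grid_step)
  vals <- delta_T_tlm(1, k, g, dd)
  i <- which.max(vals)
  lo <- dd[max(i - 1, 1)]
  hi <- dd[min(i + 1, length(dd))]
  stats::optimize(function(d) delta_T_tlm(1, k, g, d),
                  interval = c(lo, hi), maximum = TRUE,
                  tol = 1e-10)$maximum
}

#' Resonant length versus insulation thickness
#'
#' Recomputes the insulated-conductor wavenumber and the resonant length
#' over a grid of insulation outer radii, holding the conductor radius,
#' insulation permittivity, embedding medium and frequency fixed. For
#' typical device leads in tissue the resonant length increases steadily
#' with insulation thickness.
#'
#' @param geometry Base [wire_geometry()]; its `b` anchors the sweep.
#' @param medium [material_properties()] of the embedding medium.
#' @param frequency Frequency in Hz.
#' @param b Vector of insulation outer radii in m to evaluate (each
#'   > `a`); default `seq(b0, 3 b0, length.out = 21)`.
#' @param kind,gamma Model family and reflection coefficient passed to
#'   [resonant_length()].
#' @return A data frame with columns `b_m`, `kR`, `kI`, `u`,
#'   `d_res_m`.
#' @export
insulation_thickness_sweep <- function(geometry, medium, frequency,
                                       b = NULL, kind = "tlm", gamma = 1) {
  stopifnot(inherits(geometry, "wire_geometry"),
            inherits(medium, "material_properties"))
  if (is.null(b)) {
    b0 <- geometry$insulation_outer_radius_b
    b <- seq(b0, 3 * b0, length.out = 21)
  }
  if (any(b <= geometry$conductor_radius_a))
    stop("all `b` values must exceed the conductor radius", call. = FALSE)
  kt <- medium_wavenumber(medium, frequency)
  ki <- insulator_wavenumber(geometry$insulation_relative_permittivity, frequency)
  rows <- lapply(b, function(bi) {
    gi <- wire_geometry(geometry$conductor_radius_a, bi,
                        geometry$insulation_relative_permittivity)
    k <- king_wavenumber(ki, kt, gi)
    data.frame(b_m = bi, kR = k$kR, kI = k$kI, u = loss_ratio(k),
               d_res_m = resonant_length(transfer_model(kind, k, gamma)))
  })
  do.call(rbind, rows)
}
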