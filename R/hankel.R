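# Hankel functions of the first kind for complex argument.
#
# Base R's besselJ/besselY accept only real arguments, while insulated
# antenna theory needs H0^(1)(z) and H1^(1)(z) at the complex argument
# kt*b. The arguments arising from physically meaningful wire geometries
# are small (|kt*b| << 1 for sub-millimetre insulation in tissue), so the
# ascending series of J_n and Y_n are the natural evaluation: they are
# exact power series with factorial-fast convergence and negligible
# cancellation for |z| below roughly 10.

MAX_HANKEL_ABS <- 10
EULER_GAMMA <- 0.57721566490153286061

# Ascending-series J0, J1, Y0, Y1 for a single complex z.
.bessel_series <- function(z) {
  q <- -(z * z) / 4        # successive-term ratio numerator
  # J0 = sum_m q^m / (m!)^2 ; J1 = (z/2) sum_m q^m / (m!(m+1)!)
  # Y0, Y1 need the harmonic-number weighted companions.
  j0 <- 0 + 0i; j1s <- 0 + 0i; y0s <- 0 + 0i; y1s <- 0 + 0i
  term0 <- 1 + 0i          # q^m/(m!)^2
  term1 <- 1 + 0i          # q^m/(m!(m+1)!)
  h <- 0                   # harmonic number H_m
  for (m in 0:60) {
    j0  <- j0 + term0
    j1s <- j1s + term1
    y0s <- y0s + term0 * h
    y1s <- y1s + term1 * (2 * h + 1 / (m + 1))
    if (m >= 2 && Mod(term0) < 1e-18 * max(Mod(j0), 1)) break
    h <- h + 1 / (m + 1)
    term0 <- term0 * q / ((m + 1)^2)
    term1 <- term1 * q / ((m + 1) * (m + 2))
  }
  j1 <- (z / 2) * j1s
  lg <- log(z / 2) + EULER_GAMMA
  y0 <- (2 / pi) * (lg * j0 - y0s)
  # A&S 9.1.11 specialised to n = 1 (psi(m+1) + psi(m+2) = 2H_m + 1/(m+1) - 2*gamma)
  y1 <- (2 / pi) * (lg * j1 - 1 / z - (z / 4) * y1s)
  list(j0 = j0, j1 = j1, y0 = y0, y1 = y1)
}

#' Hankel function of the first kind, orders 0 and 1, complex argument
#'
#' Evaluates `H_n^(1)(z) = J_n(z) + i Y_n(z)` for `n` in `{0, 1}` by the
#' ascending power series of the Bessel functions, which is accurate for
#' the small-to-moderate arguments (`|z| <= 10`) that occur for insulated
#' wires embedded in tissue. Larger arguments are refused rather than
#' returned inaccurately.
#'
#' @param n Order, 0 or 1.
#' @param z Complex (or real) argument vector, `|z| <= 10`, `z != 0`.
#' @return Complex vector of the same length as `z`.
#' @examples
#' hankel_h1(0, 0.016 + 0.0058i)
#' @export
hankel_h1 <- function(n, z) {
  if (!n %in% c(0, 1)) stop("order `n` must be 0 or 1", call. = FALSE)
  z <- as.complex(z)
  if (any(z == 0)) stop("Hankel functions are singular at z = 0", call. = FALSE)
  if (any(Mod(z) > MAX_HANKEL_ABS)) {
    stop("series evaluation of hankel_h1() is limited to |z| <= ",
         MAX_HANKEL_ABS, call. = FALSE)
  }
  vapply(z, function(zz) {
    s <- .bessel_series(zz)
    if (n == 0) s$j0 + 1i * s$y0 else s$j1 + 1i * s$y1
  }, complex(1))
}
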