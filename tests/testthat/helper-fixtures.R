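# Shared fixtures and independent oracles.

# ASTM gel phantom and the experimental wire geometry.
astm_gel <- material_properties(80, 0.47)
exp_geometry <- wire_geometry(0.390e-3, 0.625e-3, 2.3)

# Insulated-conductor wavenumber pipeline at a field strength.
king_pipeline <- function(B) {
  f <- larmor_frequency(B)
  kt <- medium_wavenumber(astm_gel, f)
  ki <- insulator_wavenumber(2.3, f)
  list(f = f, kt = kt, ki = ki,
       k = king_wavenumber(ki, kt, exp_geometry))
}

# The 15 bench wire lengths (m).
bench_lengths_m <- sort(c(2.38, 10.38, 16.38, 20.38, 21.38, 22.38, 26.38,
                          29.38, 32.78, 35.78, 39.78, 40.78, 41.78, 25.78,
                          50.78) / 100)

# Quadrature oracle for the constant-field voltage integral: integrates
# Re and Im of h(l) separately with stats::integrate, independent of the
# closed forms and of the midpoint-rule path integrator.
quad_voltage <- function(E, h_fun, d, rel.tol = 1e-10) {
  re <- stats::integrate(function(l) Re(E * h_fun(l)), 0, d,
                         rel.tol = rel.tol, subdivisions = 500L)$value
  im <- stats::integrate(function(l) Im(E * h_fun(l)), 0, d,
                         rel.tol = rel.tol, subdivisions = 500L)$value
  complex(real = re, imaginary = im)
}

# 30-digit arbitrary-precision reference values for H_n^(1)(z)
# (frozen from an independent multiple-precision evaluation).
hankel_reference <- list(
  list(z = 0.016 + 0.0058i,
       h0 = 0.77840809203323136 - 2.6668866028677582i,
       h1 = -12.733335532569152 - 35.18913019277337i),
  list(z = 0.5 + 0.2i,
       h0 = 0.6646650537912456 - 0.44685020720430163i,
       h1 = -0.18514503289458398 - 1.2198293837127674i),
  list(z = 2 + 1i,
       h0 = 0.11221517779606792 + 0.15428168525601326i,
       h1 = 0.19121655078657474 - 0.096248131988248558i),
  list(z = 5 + 0.1i,
       h0 = -0.16335864248711407 - 0.27739533734811352i,
       h1 = -0.2954018860551402 + 0.13701994808629534i),
  list(z = 0.001 + 0.0001i,
       h0 = 0.9365484780995527 - 4.4682493830759957i,
       h1 = -63.030953028101885 - 630.31895275702903i))

# Published g(u) table: u, SEM root, open-circuit TLM root.
g_table <- matrix(c(
  0,    1,        1,
  0.05, 0.970445, 0.997526,
  0.1,  0.944714, 0.990407,
  0.15, 0.921981, 0.979433,
  0.2,  0.901668, 0.965641,
  0.25, 0.883350, 0.950053,
  0.3,  0.866706, 0.933533,
  0.35, 0.851487, 0.916733,
  0.4,  0.837496, 0.900104,
  0.45, 0.824574, 0.883939,
  0.5,  0.812591, 0.868413,
  0.6,  0.791026, 0.839597,
  0.7,  0.772124, 0.813860,
  0.8,  0.755394, 0.791024,
  0.9,  0.740465, 0.770782,
  1.0,  0.727052, 0.752809,
  5,    0.562788, 0.562833), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("u", "g_sem", "g_tlm_open")))

# Config file matching the bench setup, for CLI tests.
write_test_config <- function(path = tempfile(fileext = ".yaml"),
                              field_strength = c(1.5, 3)) {
  writeLines(c(
    "relative_permittivity: 80",
    "conductivity: 0.47",
    "conductor_radius_a_mm: 0.390",
    "insulation_outer_radius_b_mm: 0.625",
    "insulation_relative_permittivity: 2.3",
    paste0("field_strength_T: [", paste(field_strength, collapse = ", "), "]")),
    path)
  path
}
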