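k15 <- king_pipeline(1.5)$k
k3 <- king_pipeline(3)$k

test_that("transfer functions satisfy the boundary condition h(0) = 1", {
  expect_equal(sem_transfer(k3, 0), 1 + 0i)
  expect_equal(tlm_transfer(k3, 0.5, 0, 0.4), 1 + 0i)
  expect_equal(tlm_transfer(k15, 1, 0, 0.3), 1 + 0i)
})

test_that("simple exponential transfer decays and hits -1 at half wavelength", {
  kr <- wavenumber(10, 0)
  expect_equal(sem_transfer(kr, pi / 10), -1 + 0i)
  l <- seq(0, 1, by = 0.01)
  expect_true(all(Mod(sem_transfer(k3, l)) <= 1 + 1e-14))
  expect_true(all(diff(Mod(sem_transfer(k3, l))) <= 1e-14))
  expect_error(sem_transfer(k3, -0.1), ">= 0")
})

test_that("transmission line model reduces to the simple exponential at gamma = 0", {
  l <- seq(0, 0.4, by = 0.05)
  expect_equal(tlm_transfer(k3, 0, l, 0.4), sem_transfer(k3, l),
               tolerance = 1e-12)
  d <- c(0.1, 0.25, 0.4)
  expect_equal(closed_form_voltage_tlm(2 + 1i, k3, 0, d),
               closed_form_voltage_sem(2 + 1i, k3, d), tolerance = 1e-12)
  expect_equal(delta_T_tlm(1, k3, 0, d), delta_T_sem(1, k3, d),
               tolerance = 1e-12)
})

test_that("lossless open-circuit resonance is flagged as singular", {
  kr <- wavenumber(10, 0)
  d <- pi / 10  # e^{-2ikd} = 1
  expect_error(tlm_transfer(kr, 1, 0.05, d), "singular")
  expect_error(closed_form_voltage_tlm(1, kr, 1, d), "singular")
  expect_error(tlm_transfer(k3, 1, c(-0.01), 0.4), "\\[0, d\\]")
})

test_that("closed-form voltages match the quadrature oracle", {
  expect_equal(closed_form_voltage_sem(3 + 0i, k3, 0), 0 + 0i)
  kr <- wavenumber(10, 0)
  expect_lt(Mod(closed_form_voltage_sem(1 + 0i, kr, 2 * pi / 10)), 1e-14)
  set.seed(7)
  for (i in 1:10) {
    E <- complex(real = runif(1, -5, 5), imaginary = runif(1, -5, 5))
    k <- wavenumber(runif(1, 1, 30), -runif(1, 0, 5))
    d <- runif(1, 0.01, 0.6)
    v_sem <- closed_form_voltage_sem(E, k, d)
    o_sem <- quad_voltage(E, function(l) sem_transfer(k, l), d)
    expect_lt(Mod(v_sem - o_sem) / Mod(o_sem), 1e-6)
    g <- runif(1, 0, 0.9)
    v_tlm <- closed_form_voltage_tlm(E, k, g, d)
    o_tlm <- quad_voltage(E, function(l) tlm_transfer(k, g, l, d), d)
    expect_lt(Mod(v_tlm - o_tlm) / Mod(o_tlm), 1e-6)
  }
})

test_that("temperature rise equals the squared voltage magnitude", {
  d <- seq(0.01, 0.8, by = 0.01)
  expect_equal(delta_T_sem(2, k15, d),
               Mod(closed_form_voltage_sem(2 + 0i, k15, d))^2,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    k <- wavenumber(runif(1, 1, 30), -runif(1, 0, 5))
    g <- runif(1, 0, 1)
    dd <- runif(5, 0.01, 0.8)
    expect_equal(delta_T_tlm(1.5, k, g, dd),
                 Mod(closed_form_voltage_tlm(1.5 + 0i, k, g, dd))^2,
                 tolerance = 1e-10)
  }
  # complex reflection coefficient routed through |V|^2
  g <- 0.3 + 0.2i
  dd <- c(0.1, 0.3)
  expect_equal(delta_T_tlm(1, k3, g, dd),
               Mod(closed_form_voltage_tlm(1 + 0i, k3, g, dd))^2,
               tolerance = 1e-12)
})

test_that("temperature rise is non-negative and zero at zero length", {
  d <- seq(0, 1, by = 0.005)
  expect_true(all(delta_T_sem(1, k15, d) >= 0))
  expect_true(all(delta_T_tlm(1, k15, 0.7, d) >= 0))
  expect_equal(delta_T_sem(1, k3, 0), 0)
  expect_equal(delta_T_tlm(1, k3, 1, 0), 0)
})

test_that("short-wire limits are quadratic with the expected prefactors", {
  for (k in list(k15, k3)) {
    d <- 1e-3 / Mod(as.complex(k))  # kd = 1e-3
    expect_equal(delta_T_sem(2, k, d) / (2^2 * d^2), 1, tolerance = 0.01)
    expect_equal(delta_T_tlm(2, k, 1, d) / (2^2 * d^2), 0.25,
                 tolerance = 0.01 * 0.25 / 1)
  }
})

test_that("the k = 0 (unity transfer function) limit is V = E d", {
  k0 <- wavenumber(0, 0)
  expect_equal(closed_form_voltage_sem(3 + 0i, k0, 0.2), 0.6 + 0i)
  expect_equal(delta_T_sem(3, k0, 0.2), (3 * 0.2)^2)
  expect_equal(delta_T_tlm(3, k0, 0.5, 0.2), (3 * 0.2)^2)
})

test_that("numerical line integral converges to the closed form", {
  m <- transfer_model("sem", k3)
  E0 <- c(0, 0, 5 + 0i)
  d <- 0.3
  p1 <- straight_path(c(0, 0, 0), c(0, 0, 1), d, 1e-3)
  v1 <- numerical_voltage(E0, p1, m)
  ref <- closed_form_voltage_sem(5 + 0i, k3, d)
  expect_lt(Mod(v1 - ref) / Mod(ref), 1e-4)
  # halving the step at least halves the error (first-order or better)
  err <- vapply(c(4e-3, 2e-3, 1e-3), function(s) {
    Mod(numerical_voltage(E0, straight_path(c(0, 0, 0), c(0, 0, 1), d, s),
                          m, max_segment = s) - ref)
  }, numeric(1))
  expect_lt(err[2] / err[1], 0.6)
  expect_lt(err[3] / err[2], 0.6)
  # transmission line model too
  mt <- transfer_model("tlm", k3, gamma = 0.5)
  vt <- numerical_voltage(E0, p1, mt)
  rt <- closed_form_voltage_tlm(5 + 0i, k3, 0.5, d)
  expect_lt(Mod(vt - rt) / Mod(rt), 1e-4)
})

test_that("zero field integrates to zero voltage", {
  p <- straight_path(c(0, 0, 0), c(0, 0, 1), 0.2, 1e-2)
  expect_equal(numerical_voltage(c(0, 0, 0), p, transfer_model("sem", k3)),
               0 + 0i)
})

test_that("tip- and IPG-referenced TLM forms agree in |V| for a symmetric field", {
  d <- 0.35
  p <- straight_path(c(0, 0, 0), c(0, 0, 1), d, 1e-3)
  E0 <- c(0, 0, 3 + 2i)
  for (g in c(0.3, 0.8, 1)) {
    v_tip <- numerical_voltage(E0, p, transfer_model("tlm", k15, g))
    v_ipg <- numerical_voltage(E0, p, transfer_model("tlm", k15, g, form = "ipg"))
    # identical up to midpoint-rule discretisation of the two parametrisations
    expect_equal(Mod(v_tip), Mod(v_ipg), tolerance = 1e-6)
  }
})

test_that("heating curves are exportable and re-importable", {
  m <- transfer_model("tlm", k15, gamma = 1)
  hc <- heating_curve(m, seq(0.05, 0.6, by = 0.05))
  expect_s3_class(hc, "heating_curve")
  expect_true(all(hc$relative_delta_T >= 0))
  expect_equal(hc$relative_delta_T, hc$abs_voltage^2, tolerance = 1e-12)
  csv <- tempfile(fileext = ".csv")
  write_heating_curve(hc, csv)
  back <- read_heating_curve(csv)
  expect_equal(back$relative_delta_T, hc$relative_delta_T, tolerance = 1e-12)
  js <- tempfile(fileext = ".json")
  write_heating_curve(hc, js)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$model$kind, "tlm")
  expect_equal(meta$model$kR, k15$kR)
})
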