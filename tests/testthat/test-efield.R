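make_affine_field <- function() {
  x <- seq(-0.2, 0.2, by = 0.05)
  y <- seq(-0.1, 0.1, by = 0.05)
  z <- seq(-0.3, 0.3, by = 0.1)
  f <- function(cx, cy, cz, c0) {
    a <- array(0 + 0i, dim = c(length(x), length(y), length(z)))
    for (i in seq_along(x)) for (j in seq_along(y)) for (l in seq_along(z))
      a[i, j, l] <- c0 + cx * x[i] + cy * y[j] + cz * z[l]
    a
  }
  efield_grid(x, y, z,
              f(1 + 2i, 0.5, -1i, 3),
              f(-2, 1i, 0.25, 1 - 1i),
              f(0.1, -0.3 + 1i, 2, 10))
}

test_that("trilinear interpolation is exact for affine complex fields", {
  fld <- make_affine_field()
  set.seed(5)
  pts <- cbind(runif(30, -0.2, 0.2), runif(30, -0.1, 0.1), runif(30, -0.3, 0.3))
  ev <- interpolate_field(fld, pts)
  expect_equal(ev[, 1], 3 + (1 + 2i) * pts[, 1] + 0.5 * pts[, 2] - 1i * pts[, 3],
               tolerance = 1e-12)
  expect_equal(ev[, 3], 10 + 0.1 * pts[, 1] + (-0.3 + 1i) * pts[, 2] + 2 * pts[, 3],
               tolerance = 1e-12)
})

test_that("out-of-domain queries fail naming the coordinate", {
  fld <- make_affine_field()
  expect_error(interpolate_field(fld, cbind(0.5, 0, 0)), "x = 0.5")
  expect_error(interpolate_field(fld, cbind(0, 0, -1)), "z = -1")
})

test_that("tangential projection obeys orthogonality and direction cosines", {
  p_z <- straight_path(c(0, 0, -0.1), c(0, 0, 1), 0.2, 0.01)
  # purely transverse field projects to zero
  expect_equal(tangential_component(c(1 + 1i, 0, 0), p_z),
               rep(0 + 0i, 20), tolerance = 1e-14)
  # aligned constant field projects to itself
  expect_equal(tangential_component(c(0, 0, 4 + 1i), p_z),
               rep(4 + 1i, 20), tolerance = 1e-14)
  # tilted path picks up cos(theta)
  th <- pi / 6
  p_t <- straight_path(c(0, 0, -0.1), c(sin(th), 0, cos(th)), 0.2, 0.01)
  expect_equal(tangential_component(c(0, 0, 2), p_t),
               rep(2 * cos(th) + 0i, 20), tolerance = 1e-12)
})

test_that("straight paths are evenly sampled with exact arc length", {
  p <- straight_path(c(0, 0, 0), c(0, 0, 1), 0.5, 0.001)
  expect_equal(nrow(p$points), 501)
  expect_equal(total_length(p), 0.5, tolerance = 1e-12)
  p2 <- straight_path(c(0.1, -0.2, 0), c(1, 1, 1), 0.3, 0.007)
  expect_equal(total_length(p2), 0.3, tolerance = 1e-12)
  seg <- path_segments(p2)
  spread <- apply(seg$unit, 2, function(col) diff(range(col)))
  expect_true(all(spread < 1e-12))  # all segments parallel
  expect_error(straight_path(c(0, 0, 0), c(0, 0, 0), 0.1, 0.01), "nonzero")
  expect_error(wire_path(matrix(c(0, 0, 0, 0, 0, 0), 2, byrow = TRUE)),
               "distinct")
})

test_that("refine_path preserves geometry while shortening segments", {
  p <- wire_path(rbind(c(0, 0, 0), c(0, 0, 0.1), c(0, 0.05, 0.1)))
  r <- refine_path(p, 0.004)
  expect_equal(total_length(r), total_length(p), tolerance = 1e-12)
  expect_lte(max(path_segments(r)$length), 0.004 + 1e-15)
})

test_that("E-field grid files round-trip through the text format", {
  fld <- make_affine_field()
  tf <- tempfile(fileext = ".tsv")
  write_efield_grid(fld, tf)
  back <- read_efield_grid(tf)
  expect_equal(back$x, fld$x)
  expect_equal(back$Ez, fld$Ez, tolerance = 1e-12)
  expect_equal(back$Ex, fld$Ex, tolerance = 1e-12)
  # missing column detected
  df <- utils::read.table(tf, header = TRUE, sep = "\t")
  df$ImEz <- NULL
  tf2 <- tempfile(fileext = ".tsv")
  utils::write.table(df, tf2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_efield_grid(tf2), "ImEz")
})

test_that("wire path CSV round-trips", {
  p <- straight_path(c(0.1, 0, -0.2), c(0, 1, 2), 0.25, 0.01)
  tf <- tempfile(fileext = ".csv")
  write_wire_path(p, tf)
  expect_equal(read_wire_path(tf)$points, p$points, tolerance = 1e-12)
})

test_that("synthetic body-coil field has the intended spatial structure", {
  spec <- synthetic_field_spec(amplitude = 100)
  x <- seq(-0.21, 0.21, by = 0.01)
  y <- seq(-0.05, 0.05, by = 0.025)
  z <- seq(-0.325, 0.325, by = 0.015)
  fld <- synthetic_body_coil_field(spec, x, y, z)
  iz0 <- which.min(abs(z)); ix0 <- which.min(abs(x))
  # |Ez| minimal on the midline, maximal at the lateral edge at z-centre
  mid <- Mod(fld$Ez[ix0, 1, iz0])
  edge <- Mod(fld$Ez[1, 1, iz0])
  expect_lt(mid, edge)
  expect_equal(max(Mod(fld$Ez)), edge, tolerance = 1e-12)
  # transverse components stay below 10% of the Ez peak
  expect_lte(max(Mod(fld$Ex)), 0.1 * max(Mod(fld$Ez)))
  expect_lte(max(Mod(fld$Ey)), 0.1 * max(Mod(fld$Ez)))
})

test_that("line integral through the synthetic field is step-converged", {
  spec <- synthetic_field_spec(amplitude = 100)
  fld <- synthetic_body_coil_field(spec,
                                   seq(-0.21, 0.21, by = 0.01),
                                   seq(-0.05, 0.05, by = 0.025),
                                   seq(-0.325, 0.325, by = 0.005))
  m <- transfer_model("sem", king_pipeline(1.5)$k)
  start <- c(0.18, 0, -0.15)
  v_ref <- numerical_voltage(fld, straight_path(start, c(0, 0, 1), 0.3, 1e-4),
                             m, max_segment = 1e-4)
  v1 <- numerical_voltage(fld, straight_path(start, c(0, 0, 1), 0.3, 1e-3), m)
  v2 <- numerical_voltage(fld, straight_path(start, c(0, 0, 1), 0.3, 5e-4),
                          m, max_segment = 5e-4)
  expect_lt(Mod(v1 - v_ref) / Mod(v_ref), 1e-3)
  expect_lte(Mod(v2 - v_ref), Mod(v1 - v_ref) + 1e-15)
  # a lateral wire sees a stronger field than predicted on the midline
  expect_gt(Mod(v_ref), 0)
})

test_that("synthetic measurements are reproducible and invertible", {
  k <- king_pipeline(1.5)$k
  m <- transfer_model("tlm", k, gamma = 0.25)
  lens <- seq(0.05, 0.5, length.out = 10)
  a <- synthetic_measurements(m, 40, lens, noise_sd = 1, tg_spread = 3, seed = 21)
  b <- synthetic_measurements(m, 40, lens, noise_sd = 1, tg_spread = 3, seed = 21)
  expect_identical(a, b)
  # noiseless, no TG spread: exact scaled model curve
  clean <- synthetic_measurements(m, 40, lens, seed = 1)
  expect_equal(clean$delta_T_C, 40 * delta_T(m, lens), tolerance = 1e-12)
  # noiseless with TG spread: tg_correct inverts the power perturbation
  pert <- synthetic_measurements(m, 40, lens, noise_sd = 0, tg_spread = 5,
                                 seed = 2, tg_ref = 120)
  fixed <- tg_correct(pert$delta_T_C, pert$tg_aps, 120)
  expect_equal(fixed, 40 * delta_T(m, lens), tolerance = 1e-10)
  # ... and the fit recovers the generating scale exactly
  fit <- fit_scale(delta_T(m, lens), fixed)
  expect_equal(fit$scale, 40, tolerance = 1e-10)
  expect_lt(fit$rmse, 1e-8)
})
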