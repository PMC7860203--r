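test_that("solid-body rotation has curl 2*omega everywhere, at any resolution", {
  for (n in c(21, 41, 81)) {
    pl <- make_rotation_plane(n, omega = 10)
    cf <- curl_field(pl)
    vals <- cf$values[cf$mask]
    # linear field: central AND one-sided differences are exact
    expect_equal(max(abs(vals - 20)), 0, tolerance = 1e-10)
    expect_equal(average_curl(pl), 20, tolerance = 1e-10)
  }
})

test_that("uniform translation and simple shear have the closed-form curl", {
  g <- make_grid(31)
  trans <- velocity_plane(u = g$X * 0 + 0.3, v = g$X * 0 - 0.1, spacing = g$h)
  expect_equal(average_curl(trans), 0, tolerance = 1e-12)
  k <- 2.5
  shear <- velocity_plane(u = k * g$Y, v = g$X * 0, spacing = g$h)
  cf <- curl_field(shear)
  expect_equal(mean(cf$values[cf$mask]), -k, tolerance = 1e-10)
  expect_equal(average_curl(shear, signed = TRUE), -k, tolerance = 1e-10)
  expect_equal(average_curl(shear), k, tolerance = 1e-10)   # magnitude
})

test_that("irrotational fields have vanishing curl within O(h^2)", {
  g <- make_grid(61)
  # gradient field u = x, v = y
  rad <- velocity_plane(u = g$X, v = g$Y, spacing = g$h)
  expect_equal(average_curl(rad), 0, tolerance = 1e-10)
  # smooth radial source: u = x f(r^2), v = y f(r^2) is curl-free
  s <- g$X^2 + g$Y^2
  src <- velocity_plane(u = g$X / (1 + s), v = g$Y / (1 + s), spacing = g$h)
  expect_lt(average_curl(src), 1e-3)
})

test_that("curl converges at second order on a smooth vortex", {
  # u = -y e^{-r^2}, v = x e^{-r^2}: curl = 2 e^{-r^2} (1 - r^2); the
  # discrete average is compared with the analytic curl averaged over the
  # same section sample, isolating the differencing error
  errs <- vapply(c(41, 81, 161), function(n) {
    g <- make_grid(n)
    e <- exp(-(g$X^2 + g$Y^2))
    pl <- velocity_plane(u = -g$Y * e, v = g$X * e, spacing = g$h)
    analytic_mean <- mean(2 * e * (1 - (g$X^2 + g$Y^2)))
    abs(average_curl(pl, signed = TRUE) - analytic_mean)
  }, 0)
  ratios <- errs[-3L] / errs[-1L]
  expect_true(all(ratios > 2.5))   # ~4x per halving
  # and the continuum section mean is approached as the grid refines
  sect_mean <- local({
    A <- integrate(function(x) exp(-x^2), -1, 1, rel.tol = 1e-12)$value
    B <- integrate(function(x) x^2 * exp(-x^2), -1, 1, rel.tol = 1e-12)$value
    (2 * A^2 - 4 * A * B) / 4
  })
  g <- make_grid(161)
  e <- exp(-(g$X^2 + g$Y^2))
  pl <- velocity_plane(u = -g$Y * e, v = g$X * e, spacing = g$h)
  expect_lt(abs(average_curl(pl, signed = TRUE) - sect_mean), 0.01)
})

test_that("average curl is invariant under 90-degree axis rotation", {
  # off-centre vortex, evaluated in original and rotated coordinates
  field_u <- function(x, y) -(y - 0.3) * exp(-(x - 0.2)^2 - (y - 0.3)^2)
  field_v <- function(x, y) (x - 0.2) * exp(-(x - 0.2)^2 - (y - 0.3)^2)
  g <- make_grid(81)
  pl <- velocity_plane(u = field_u(g$X, g$Y), v = field_v(g$X, g$Y),
                       spacing = g$h)
  # rotated frame: (x', y') = (y, -x); u' = -v(y', -x'), v' = u(y', -x')
  pl_rot <- velocity_plane(u = -field_v(g$Y, -g$X), v = field_u(g$Y, -g$X),
                           spacing = g$h)
  expect_equal(average_curl(pl_rot), average_curl(pl), tolerance = 1e-10)
})

test_that("thin masks without derivable points are rejected", {
  u <- matrix(0, 5, 5); v <- matrix(0, 5, 5)
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE      # isolated point
  expect_error(curl_field(velocity_plane(u, v, 0.1, m)), "too thin")
})

test_that("pearson_r matches the covariance-formula oracle", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.9, 3.1, 2.6, 4.2, 4.9)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_oracle, tolerance = 1e-14)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(x[1:2], y[1:2]), "at least 3")
})

test_that("curl-pressure correlation behaves on the surrogate model", {
  Q <- default_flow_grid()
  drops <- 0.003 * Q + 1.5e-6 * Q^2
  # exactly proportional series
  expect_equal(curl_pressure_correlation(3 * drops, drops), 1)
  # noiseless superlinear curl against the quadratic drop: near-perfect
  curls <- 0.006 * Q^1.4
  expect_gt(curl_pressure_correlation(curls, drops), 0.97)
  # breaking the pairing strictly lowers the correlation
  expect_lt(curl_pressure_correlation(rev(curls), drops),
            curl_pressure_correlation(curls, drops))
})

test_that("generated planes carry their analytic curl", {
  pl <- generate_velocity_plane(Q = 400, radius = 4, swirl = 0.4, grid_n = 81)
  expect_equal(average_curl(pl), attr(pl, "analytic_curl"), tolerance = 1e-8)
  # no swirl, no curl
  pl0 <- generate_velocity_plane(Q = 400, radius = 4, swirl = 0)
  expect_equal(average_curl(pl0), 0, tolerance = 1e-12)
  # linear in swirl
  pl2 <- generate_velocity_plane(Q = 400, radius = 4, swirl = 0.8, grid_n = 81)
  expect_equal(average_curl(pl2), 2 * average_curl(pl), tolerance = 1e-8)
})

test_that("a plane tuned to the measured jugular curl reproduces it", {
  # patient 1 at 400 mL/min reports 26.41 1/s average curl; a solid-body
  # swirl with rim speed chosen from the closed form 2*swirl*V/R hits it
  Q <- 400; R_mm <- 4
  V <- mlmin_to_m3s(Q) / (pi * mm_to_m(R_mm)^2)
  target <- jugular_curl()$patient1[jugular_curl()$flow == 400]
  swirl <- target * mm_to_m(R_mm) / (2 * V)
  pl <- generate_velocity_plane(Q, R_mm, swirl, grid_n = 101)
  expect_lt(abs(average_curl(pl) - target) / target, 0.02)
})

test_that("velocity plane text round trip is lossless", {
  pl <- make_rotation_plane(15, omega = 3)
  p <- withr::local_tempfile(fileext = ".txt")
  write_velocity_plane(pl, p)
  back <- read_velocity_plane(p)
  expect_equal(back$u, pl$u, tolerance = 1e-9)
  expect_equal(back$v, pl$v, tolerance = 1e-9)
  expect_equal(back$mask, pl$mask)
  expect_equal(back$spacing, pl$spacing, tolerance = 1e-12)
})

test_that("legacy VTK structured-points planes are read correctly", {
  nx <- 4L; ny <- 3L; sp <- 0.002
  u <- matrix(seq_len(nx * ny), ny, nx, byrow = TRUE)
  v <- -2 * u
  p <- withr::local_tempfile(fileext = ".vtk")
  pts <- character(0)
  for (j in seq_len(ny)) for (i in seq_len(nx))
    pts <- c(pts, sprintf("%g %g 0", u[j, i], v[j, i]))
  writeLines(c(
    "# vtk DataFile Version 3.0", "plane", "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", nx, ny),
    "ORIGIN 0 0 0",
    sprintf("SPACING %g %g 1", sp, sp),
    sprintf("POINT_DATA %d", nx * ny),
    "VECTORS velocity float",
    pts), p)
  pl <- read_velocity_plane_vtk(p)
  expect_equal(pl$u, u)
  expect_equal(pl$v, v)
  expect_equal(pl$spacing, sp)
  expect_true(all(pl$mask))
})
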