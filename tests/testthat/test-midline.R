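strip_mask <- function(height = 400, width = 100, rows = 1:400, cols = 41:60) {
  m <- matrix(0L, height, width)
  m[rows, cols] <- 1L
  m
}

test_that("the largest 8-connected component is selected as the spine", {
  m <- matrix(0L, 120, 120)
  m[11:20, 11:110] <- 1L          # 10x100 strip, area 1000
  m[60:62, 60:62] <- 1L           # 3x3 blob
  region <- extract_spine_region(m)
  expect_equal(region$area_px, 1000)
  expect_equal(sum(region$mask[11:20, 11:110]), 1000)

  expect_spinetrace_error(extract_spine_region(matrix(0L, 5, 5)),
                          "spinetrace_no_spine_error")
})

test_that("area ties go to the topmost-then-leftmost component", {
  m <- matrix(0L, 40, 40)
  m[1:5, 10:14] <- 1L    # starts at row 0 (0-based)
  m[21:25, 10:14] <- 1L  # starts at row 20
  region <- extract_spine_region(m)
  expect_equal(sum(region$mask[1:5, 10:14]), 25)
  expect_equal(sum(region$mask), 25)
})

test_that("diagonally touching pixels form one component", {
  m <- matrix(0L, 10, 10)
  m[cbind(1:6, 1:6)] <- 1L  # a pure diagonal
  m[9, 9] <- 1L
  region <- extract_spine_region(m)
  expect_equal(region$area_px, 6)
})

test_that("grid midpoints reproduce the row-scan oracle on a vertical strip", {
  m <- strip_mask()
  region <- extract_spine_region(m)
  mp <- compute_grid_midpoints(region, 50)
  expect_equal(mp$y, c(seq(0, 350, 50), 399))
  expect_true(all(mp$x_left == 40) && all(mp$x_right == 59))
  expect_true(all(mp$x_mid == 49.5))
  oracle <- oracle_row_midpoints(m, 50)
  expect_equal(mp[c("y", "x_left", "x_right", "x_mid")], oracle,
               ignore_attr = TRUE)

  expect_spinetrace_error(compute_grid_midpoints(region, 400),
                          "spinetrace_insufficient_midpoints_error")
})

test_that("grid midpoints are equivariant under vertical translation", {
  m <- strip_mask()
  shifted <- matrix(0L, 500, 100)
  shifted[101:500, ] <- m
  mp0 <- compute_grid_midpoints(extract_spine_region(m), 50)
  mp1 <- compute_grid_midpoints(extract_spine_region(shifted), 50)
  expect_equal(mp1$y, mp0$y + 100)
  expect_equal(mp1$x_mid, mp0$x_mid)
})

test_that("the midline spline interpolates exactly and reproduces linear data", {
  ys <- seq(0, 400, 50)
  mp <- data.frame(y = ys, x_left = 0, x_right = 0, x_mid = 10 + 0.25 * ys,
                   inclination_deg = NA_real_)
  ml <- fit_midline(mp)
  expect_lt(max(abs(ml$spline(ys) - mp$x_mid)), 1e-9)
  probe <- c(13, 77.5, 333)
  expect_equal(ml$spline(probe), 10 + 0.25 * probe, tolerance = 1e-9)
  expect_equal(ml$samples$y, 0:400)

  mp_bad <- mp; mp_bad$y[2] <- 0
  expect_spinetrace_error(fit_midline(mp_bad), "spinetrace_domain_error")
  expect_spinetrace_error(fit_midline(mp[1:3, ]), "spinetrace_domain_error")
})

test_that("the spline tracks a sampled cosine midline closely", {
  f_true <- function(y) 100 + 80 * cos(2 * pi * y / 1200)
  ml <- analytic_midline(f_true, seq(0, 1200, 50))
  yy <- 0:1200
  err <- abs(ml$spline(yy) - f_true(yy))
  expect_lt(max(err), 0.1)
})

test_that("inclinations are the signed tangent-from-vertical angles", {
  vert <- analytic_midline(function(y) rep(50, length(y)), seq(0, 400, 50))
  incl <- vert$midpoints$inclination_deg
  expect_true(all(is.na(incl[c(1, length(incl))])))
  expect_equal(incl[2:(length(incl) - 1)], rep(0, length(incl) - 2))

  shear <- analytic_midline(function(y) 0.5 * y + 20, seq(0, 400, 50))
  inner <- shear$midpoints$inclination_deg[2:8]
  expect_equal(inner, rep(atan(0.5) * 180 / pi, 7), tolerance = 1e-9)
  expect_equal(inner[1], 26.565, tolerance = 1e-3)

  mirrored <- analytic_midline(function(y) -(0.5 * y + 20), seq(0, 400, 50))
  expect_equal(mirrored$midpoints$inclination_deg[2:8], -inner, tolerance = 1e-9)
})

test_that("perpendicular-to-tangent equals tangent-from-vertical at every midpoint", {
  f <- function(y) 100 + 60 * cos(2 * pi * y / 1000)
  ml <- analytic_midline(f, seq(0, 1000, 50))
  mp <- ml$midpoints
  interior <- which(!is.na(mp$inclination_deg))
  for (i in interior) {
    s <- ml$spline(mp$y[i], deriv = 1)       # dx/dy
    tangent <- c(s, 1)                       # (x, y) direction per unit y
    perp <- c(1, -s)                         # perpendicular to the tangent
    angle_tangent_vertical <- acos(abs(sum(tangent * c(0, 1))) / sqrt(sum(tangent^2)))
    angle_perp_horizontal <- acos(abs(sum(perp * c(1, 0))) / sqrt(sum(perp^2)))
    expect_equal(angle_tangent_vertical, angle_perp_horizontal, tolerance = 1e-12)
    expect_equal(abs(mp$inclination_deg[i]),
                 angle_perp_horizontal * 180 / pi, tolerance = 1e-9)
  }
})

test_that("cubic midlines are recovered to the rasterization limit", {
  # true midline: cubic polynomial in y
  fx <- function(y) 150 + 0.12 * y - 4e-4 * y^2 + 3.5e-7 * y^3
  dfx <- function(y) 0.12 - 8e-4 * y + 3 * 3.5e-7 * y^2
  analytic_at <- function(ys) atan(dfx(ys)) * 180 / pi

  # on exact midpoints the spline reproduces the cubic's derivative
  ml0 <- analytic_midline(fx, seq(0, 800, 50))
  mp0 <- ml0$midpoints
  i0 <- !is.na(mp0$inclination_deg)
  expect_lt(max(abs(mp0$inclination_deg[i0] - analytic_at(mp0$y[i0]))), 0.01)

  # on a rasterized mask the midpoints carry +/- 0.5 px quantization, which
  # an interpolating spline turns into up to ~1 degree of local slope error
  h <- 801; w <- 320
  m <- matrix(0L, h, w)
  for (y in 0:800) {
    x <- fx(y)
    m[y + 1, (ceiling(x - 40):floor(x + 40)) + 1] <- 1L
  }
  ml <- compute_inclinations(fit_midline(
    compute_grid_midpoints(extract_spine_region(m), 50)))
  mp <- ml$midpoints
  interior <- !is.na(mp$inclination_deg)
  expect_lt(max(abs(mp$inclination_deg[interior] - analytic_at(mp$y[interior]))), 1)
})

test_that("midpoints and inclinations respect horizontal mirror symmetry", {
  fx <- cosine_fixture(amplitude = 60, wavelength = 1200)
  m <- fx$mask
  mm <- m[, ncol(m):1]
  ml <- compute_inclinations(fit_midline(
    compute_grid_midpoints(extract_spine_region(m), 50)))
  mlm <- compute_inclinations(fit_midline(
    compute_grid_midpoints(extract_spine_region(mm), 50)))
  expect_equal(mlm$midpoints$y, ml$midpoints$y)
  expect_equal(mlm$midpoints$x_mid, ncol(m) - 1 - ml$midpoints$x_mid)
  expect_equal(mlm$midpoints$inclination_deg, -ml$midpoints$inclination_deg,
               tolerance = 1e-9)
})
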