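test_that("apex detection finds the closed-form extremum of a C-curve", {
  # x(y) = 100 + 80 cos(2 pi y / 1200): reference x = 180 at y = 0,
  # d(y) = 80 (cos - 1) <= 0, single sign -> simple, apex y = 600, d = -160
  ml <- analytic_midline(function(y) 100 + 80 * cos(2 * pi * y / 1200),
                         seq(0, 1200, 50))
  ap <- detect_apexes(ml, apex_threshold = 20)
  expect_equal(ap$curve_type, "simple")
  expect_equal(ap$reference_x, 180)
  expect_equal(nrow(ap$apexes), 1L)
  expect_equal(ap$apexes$y, 600, tolerance = 1)
  expect_equal(ap$apexes$displacement, -160, tolerance = 0.01)
})

test_that("apex detection classifies an S-curve as complex with signed apexes", {
  # x(y) = 100 + 50 sin(2 pi y / 800): extrema d = +50 at y=200, -50 at y=600
  ml <- analytic_midline(function(y) 100 + 50 * sin(2 * pi * y / 800),
                         seq(0, 800, 50))
  ap <- detect_apexes(ml, apex_threshold = 20)
  expect_equal(ap$curve_type, "complex")
  expect_equal(ap$apexes$y, c(200, 600), tolerance = 1)
  expect_equal(ap$apexes$displacement, c(50, -50), tolerance = 0.01)
})

test_that("a straight midline yields a simple curve with zero displacement", {
  ml <- analytic_midline(function(y) rep(120, length(y)), seq(0, 400, 50))
  ap <- detect_apexes(ml, apex_threshold = 20)
  expect_equal(ap$curve_type, "simple")
  expect_equal(ap$apexes$displacement, 0)
  # an interior apex, so tilted vertebrae exist on both sides
  expect_gt(ap$apexes$y, 0)
  expect_lt(ap$apexes$y, 400)
})

test_that("tilted vertebrae sit at the analytic quarter-wavelength rows of a C-curve", {
  ml <- analytic_midline(function(y) 300 + 80 * cos(2 * pi * y / 1200),
                         seq(0, 1200, 50))
  ap <- detect_apexes(ml, 20)
  pairs <- select_tilted_vertebrae(ml, ap)
  expect_length(pairs, 1L)
  # oracle: argmax |atan(x'(y))| over interior grid rows per side of apex
  grid_y <- ml$midpoints$y[-c(1, nrow(ml$midpoints))]
  slope <- -80 * (2 * pi / 1200) * sin(2 * pi * grid_y / 1200)
  theta <- abs(atan(slope))
  above <- grid_y[grid_y < 600]; below <- grid_y[grid_y > 600]
  expect_equal(pairs[[1]]$upper$y, above[which.max(theta[grid_y < 600])])
  expect_equal(pairs[[1]]$lower$y, below[which.max(theta[grid_y > 600])])
  expect_equal(pairs[[1]]$upper$y, 300)
  expect_equal(pairs[[1]]$lower$y, 900)
})

test_that("inclination ties are broken by proximity to the apex", {
  ml <- analytic_midline(function(y) rep(120, length(y)), seq(0, 400, 50))
  ap <- detect_apexes(ml, 20)
  pairs <- select_tilted_vertebrae(ml, ap)
  # all interior inclinations are exactly 0: the pair hugs the apex
  expect_equal(pairs[[1]]$upper$y, max(ml$midpoints$y[ml$midpoints$y < ap$apexes$y &
                                                       !is.na(ml$midpoints$inclination_deg)]))
  expect_equal(pairs[[1]]$lower$y, min(ml$midpoints$y[ml$midpoints$y > ap$apexes$y &
                                                       !is.na(ml$midpoints$inclination_deg)]))
})

test_that("complex curves are split between apexes and measured per segment", {
  ml <- analytic_midline(function(y) 300 + 60 * sin(2 * pi * y / 1200),
                         seq(0, 1200, 50))
  ap <- detect_apexes(ml, 20)
  expect_equal(ap$curve_type, "complex")
  pairs <- select_tilted_vertebrae(ml, ap)
  expect_length(pairs, 2L)
  expect_lt(pairs[[1]]$upper$y, pairs[[1]]$lower$y)
  expect_lt(pairs[[2]]$upper$y, pairs[[2]]$lower$y)
  # upper pair within the upper half, lower pair within the lower half
  expect_true(all(c(pairs[[1]]$upper$y, pairs[[1]]$lower$y) <= 600))
  expect_true(all(c(pairs[[2]]$upper$y, pairs[[2]]$lower$y) >= 600))
})

test_that("the Cobb angle is the absolute difference of the endplate tilts", {
  expect_equal(cobb_angle(-22.73, 22.73), 45.46)
  expect_equal(cobb_angle(10, 10), 0)
  expect_equal(cobb_angle(10, -5), 15)
  expect_error(cobb_angle(95, 0))
})

test_that("the tilt-difference formula equals the perpendicular-intersection construction", {
  set.seed(11)
  for (i in 1:20) {
    th <- sort(runif(2, -80, 80))
    if (abs(th[1] - th[2]) < 1e-6) next
    # perpendiculars to endplates tilted at th (deg from horizontal) have
    # direction vectors (sin th, -cos th); angle at their intersection:
    v1 <- c(sinpi(th[1] / 180), -cospi(th[1] / 180))
    v2 <- c(sinpi(th[2] / 180), -cospi(th[2] / 180))
    inter <- acos(pmax(-1, pmin(1, sum(v1 * v2)))) * 180 / pi
    expect_equal(cobb_angle(th[1], th[2]), inter, tolerance = 1e-9)
  }
})

test_that("severity classes partition the angle axis with the documented endpoints", {
  expect_equal(classify_severity(5), "spinal curve")
  expect_equal(classify_severity(15), "mild")
  expect_equal(classify_severity(25), "moderate")
  expect_equal(classify_severity(45), "severe")
  expect_equal(classify_severity(0), "spinal curve")
  expect_equal(classify_severity(10), "mild")
  expect_equal(classify_severity(20), "moderate")
  expect_equal(classify_severity(40), "moderate")
  expect_equal(classify_severity(41), "severe")
  expect_spinetrace_error(classify_severity(-1), "spinetrace_domain_error")
  # total and single-valued over a dense grid
  grid <- seq(0, 80, by = 0.25)
  classes <- vapply(grid, classify_severity, character(1))
  expect_true(all(classes %in% c("spinal curve", "mild", "moderate", "severe")))
  expect_equal(severity_label("severe"), "Severe scoliosis")
})

test_that("end-to-end assessment recovers null and severe curvatures", {
  straight <- generate_spine_mask(synthetic_spine_spec(curve_form = "straight",
                                                       amplitude = 0))
  a0 <- assess(straight$mask)
  expect_lt(a0$measurement$angles_deg, 1)
  expect_equal(a0$measurement$severity, "spinal curve")

  fx <- cosine_fixture(80, 1200)
  a1 <- assess(fx$mask)
  expect_equal(a1$measurement$curve_type, "simple")
  expect_lt(abs(a1$measurement$angles_deg - 2 * atan(2 * pi * 80 / 1200) * 180 / pi), 2)
  expect_equal(a1$measurement$severity, "severe")
})

test_that("assessment is mirror-symmetric and translation-invariant", {
  fx <- cosine_fixture(60, 1200)
  base <- assess(fx$mask)
  mirrored <- assess(fx$mask[, ncol(fx$mask):1])
  expect_equal(mirrored$measurement$angles_deg, base$measurement$angles_deg,
               tolerance = 1e-6)
  expect_equal(mirrored$measurement$severity, base$measurement$severity)
  expect_equal(mirrored$measurement$apexes$displacement,
               -base$measurement$apexes$displacement, tolerance = 1e-6)

  cfg <- pipeline_config(rescale_height = NA)  # native resolution
  base_n <- assess(fx$mask, cfg)
  padded <- matrix(0L, nrow(fx$mask) + 70, ncol(fx$mask) + 90)
  padded[31:(30 + nrow(fx$mask)), 41:(40 + ncol(fx$mask))] <- fx$mask
  expect_equal(assess(padded, cfg)$measurement$angles_deg,
               base_n$measurement$angles_deg, tolerance = 1e-6)
})

test_that("measured Cobb angle is monotone in amplitude on clean phantoms", {
  angles <- vapply(c(0, 20, 40, 60, 80), function(A) {
    fx <- if (A == 0)
      generate_spine_mask(synthetic_spine_spec(curve_form = "straight", amplitude = 0))
    else cosine_fixture(A, 1200)
    max(assess(fx$mask)$measurement$angles_deg)
  }, numeric(1))
  expect_true(all(diff(angles) >= 0))
  truth <- 2 * atan(2 * pi * c(0, 20, 40, 60, 80) / 1200) * 180 / pi
  expect_true(all(abs(angles - truth) <= 2))
})

test_that("an empty mask and an unsplittable curve raise their own error classes", {
  expect_spinetrace_error(assess(matrix(0L, 10, 10)), "spinetrace_no_spine_error")
  # apex at the very end of the measurable range: no interior midpoint below
  ml <- analytic_midline(function(y) 100 + (y / 400)^3 * 50, seq(0, 400, 50))
  ap <- list(apexes = data.frame(y = 400, x = 150, displacement = 50),
             curve_type = "simple", reference_x = 100)
  expect_spinetrace_error(select_tilted_vertebrae(ml, ap),
                          "spinetrace_unmeasurable_curve_error")
})
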