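# Independent oracles used across the test files. These deliberately take
# the slow, first-principles route so they stay independent of the package
# implementation they check.

# Crossing-number point-in-polygon with explicit on-boundary test.
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  on_segment <- function(px, py, x1, y1, x2, y2) {
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) > 1e-9) return(FALSE)
    px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
      py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (on_segment(px, py, xs[i], ys[i], xs[j], ys[j])) return(TRUE)
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Row-scan midpoints straight off the mask, no region machinery.
oracle_row_midpoints <- function(mask, grid_interval) {
  rows <- which(rowSums(mask) > 0) - 1L
  ys <- seq(min(rows), max(rows), by = grid_interval)
  if (ys[length(ys)] != max(rows)) ys <- c(ys, max(rows))
  do.call(rbind, lapply(ys, function(y) {
    cols <- which(mask[y + 1L, ] > 0) - 1L
    data.frame(y = y, x_left = min(cols), x_right = max(cols),
               x_mid = (min(cols) + max(cols)) / 2)
  }))
}

# ICC(2,1) point estimate via stats::aov mean squares (independent route
# to the same two-way ANOVA decomposition).
oracle_icc21 <- function(a, b) {
  n <- length(a)
  d <- data.frame(score = c(a, b),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(c("a", "b"), each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# A clean cosine phantom used by several files.
cosine_fixture <- function(amplitude = 80, wavelength = 1200,
                           y_top = (2000 - wavelength) %/% 2, ...) {
  generate_spine_mask(synthetic_spine_spec(
    amplitude = amplitude, wavelength = wavelength, y_top = y_top, ...))
}

# Build a midline object directly from an analytic x(y), bypassing masks.
analytic_midline <- function(fun, ys) {
  mp <- data.frame(y = ys, x_left = fun(ys) - 10, x_right = fun(ys) + 10,
                   x_mid = fun(ys), inclination_deg = NA_real_)
  compute_inclinations(fit_midline(mp))
}

expect_spinetrace_error <- function(expr, subclass) {
  expect_error(expr, class = subclass)
}
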