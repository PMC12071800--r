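# Synthetic spine phantoms: parametric midlines rasterized to binary masks
# with closed-form Cobb angles and landmark rows, the package's
# ground-truth validation surface.

#' Specify a synthetic spine phantom
#'
#' The phantom is a vertically oriented band of half-width `half_width`
#' around a parametric midline spanning one wavelength:
#' `x(y) = center_x + A*cos(2*pi*(y - y_top)/lambda)` for a C-shaped curve
#' (`cosine_C`), the sine analogue for an S-shaped curve (`sine_S`), or a
#' vertical line (`straight`). The cosine form is the canonical recovery
#' fixture because its maximum-tilt rows (at quarter wavelength) are
#' interior to the spine, away from the excluded upper/lower limit points.
#' Optional boundary noise jitters each row's left and right edges
#' independently, emulating segmentation contour error.
#'
#' @param image_height,image_width Frame size in pixels (default 2000 x 600,
#'   the pipeline's working height).
#' @param amplitude Lateral amplitude A in pixels (>= 0).
#' @param wavelength Wavelength lambda in pixels; the spine spans one full
#'   wavelength vertically.
#' @param half_width Half-width of the band in pixels (>= 3).
#' @param center_x Midline center column.
#' @param y_top Topmost spine row.
#' @param curve_form `"cosine_C"`, `"sine_S"`, or `"straight"`.
#' @param noise_sd Standard deviation (px) of the per-row Gaussian edge
#'   jitter; 0 for a clean mask.
#' @param seed Integer seed for the jitter (ignored when `noise_sd = 0`).
#' @return An object of class `synthetic_spine_spec`.
#' @export
synthetic_spine_spec <- function(image_height = 2000, image_width = 600,
                                 amplitude = 80, wavelength = 1200,
                                 half_width = 60, center_x = 300,
                                 y_top = 400, curve_form = c("cosine_C", "sine_S", "straight"),
                                 noise_sd = 0, seed = 1L) {
  curve_form <- match.arg(curve_form)
  if (half_width < 3) st_geometry_error("half_width must be >= 3")
  if (amplitude < 0) st_geometry_error("amplitude must be >= 0")
  if (y_top < 0 || y_top + wavelength > image_height - 1)
    st_geometry_error("spine does not fit the frame vertically")
  reach <- amplitude + half_width
  if (center_x - reach < 0 || center_x + reach > image_width - 1)
    st_geometry_error("spine does not fit the frame horizontally")
  structure(list(image_height = image_height, image_width = image_width,
                 amplitude = amplitude, wavelength = wavelength,
                 half_width = half_width, center_x = center_x, y_top = y_top,
                 curve_form = curve_form, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spine_spec")
}

midline_fun <- function(spec) {
  switch(spec$curve_form,
    cosine_C = function(y) spec$center_x +
      spec$amplitude * cos(2 * pi * (y - spec$y_top) / spec$wavelength),
    sine_S = function(y) spec$center_x +
      spec$amplitude * sin(2 * pi * (y - spec$y_top) / spec$wavelength),
    straight = function(y) rep(spec$center_x, length(y)))
}

#' Analytic Cobb angle of a synthetic spine
#'
#' For the cosine C-curve the maximum midline slope is `2*pi*A/lambda` at
#' the quarter-wavelength rows, with opposite signs, so the Cobb angle is
#' `2*atan(2*pi*A/lambda)` in degrees. A straight spine has angle 0. For
#' the S-curve the value is computed numerically as the range of
#' `atan(x'(y))` over the interior rows at 1 px steps (a documented
#' numeric truth, not a closed form).
#'
#' @param spec A [synthetic_spine_spec()].
#' @return The Cobb angle in degrees.
#' @export
analytic_cobb <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spine_spec"))
  switch(spec$curve_form,
    straight = 0,
    cosine_C = 2 * atan(2 * pi * spec$amplitude / spec$wavelength) * 180 / pi,
    sine_S = {
      y <- seq(spec$y_top + 1, spec$y_top + spec$wavelength - 1)
      slope <- spec$amplitude * (2 * pi / spec$wavelength) *
        cos(2 * pi * (y - spec$y_top) / spec$wavelength)
      theta <- atan(slope) * 180 / pi
      max(theta) - min(theta)
    })
}

synthetic_truth <- function(spec) {
  lam <- spec$wavelength
  switch(spec$curve_form,
    straight = list(cobb_deg = 0, apex_rows = NA_real_,
                    tilt_extremum_rows = NA_real_, curve_type = "simple"),
    cosine_C = list(cobb_deg = analytic_cobb(spec),
                    apex_rows = spec$y_top + lam / 2,
                    tilt_extremum_rows = spec$y_top + c(lam / 4, 3 * lam / 4),
                    curve_type = "simple"),
    sine_S = list(cobb_deg = analytic_cobb(spec),
                  apex_rows = spec$y_top + c(lam / 4, 3 * lam / 4),
                  tilt_extremum_rows = spec$y_top + c(0, lam / 2, lam),
                  curve_type = "complex"))
}

#' Generate a synthetic spine mask with its ground truth
#'
#' Rasterizes the spec's midline: pixel (y, x) is foreground iff
#' `y` lies in the spine's vertical span and `|x - x(y)| <= half_width`.
#' When `noise_sd > 0`, each row's left and right boundary columns are
#' independently shifted by rounded Gaussian noise (seeded, restoring the
#' caller's RNG state), clamped so every row keeps at least 3 px of width
#' and stays inside the frame.
#'
#' @param spec A [synthetic_spine_spec()].
#' @return A list with `mask` (0/1 matrix), `truth` (list with `cobb_deg`,
#'   `apex_rows`, `tilt_extremum_rows`, `curve_type`), and `spec`.
#' @export
generate_spine_mask <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spine_spec"))
  h <- spec$image_height; w <- spec$image_width
  ys <- seq(spec$y_top, spec$y_top + spec$wavelength)
  xm <- midline_fun(spec)(ys)
  left <- ceiling(xm - spec$half_width)
  right <- floor(xm + spec$half_width)
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(spec$seed)
    left <- left + round(stats::rnorm(length(ys), 0, spec$noise_sd))
    right <- right + round(stats::rnorm(length(ys), 0, spec$noise_sd))
    # keep every row >= 3 px wide, centered where it was
    narrow <- right - left < 2
    ctr <- floor((left + right) / 2)
    left[narrow] <- ctr[narrow] - 1L
    right[narrow] <- ctr[narrow] + 1L
  }
  left <- pmax(0L, pmin(w - 3L, as.integer(left)))
  right <- pmax(left + 2L, pmin(w - 1L, as.integer(right)))
  mask <- matrix(0L, nrow = h, ncol = w)
  for (i in seq_along(ys))
    mask[ys[i] + 1L, (left[i] + 1L):(right[i] + 1L)] <- 1L
  list(mask = mask, truth = synthetic_truth(spec), spec = spec)
}

#' Deterministic battery of synthetic spine fixtures
#'
#' The standard validation battery: one straight spine, the 12-point clean
#' cosine C-curve grid with amplitude A in {20, 40, 60, 80} px crossed
#' with wavelength lambda in {1000, 1200, 1600} px, one S-shaped complex
#' case, and one noisy cosine C-curve (edge jitter SD 2 px). All phantoms
#' live in a 2000 x 600 frame, vertically centered.
#'
#' @param seed Integer seed controlling the noisy fixture.
#' @return A list of 15 fixtures, each a list with `spec`, `mask`,
#'   `truth`, and a descriptive `name`.
#' @export
fixture_suite <- function(seed = 1L) {
  center_top <- function(lam) as.integer((2000 - lam) %/% 2)
  specs <- list(list(name = "straight",
                     spec = synthetic_spine_spec(curve_form = "straight",
                                                 amplitude = 0, wavelength = 1200,
                                                 y_top = center_top(1200))))
  for (A in c(20, 40, 60, 80)) for (lam in c(1000, 1200, 1600)) {
    specs[[length(specs) + 1L]] <- list(
      name = sprintf("cosine_A%d_L%d", A, lam),
      spec = synthetic_spine_spec(amplitude = A, wavelength = lam,
                                  y_top = center_top(lam)))
  }
  specs[[length(specs) + 1L]] <- list(
    name = "sine_S",
    spec = synthetic_spine_spec(curve_form = "sine_S", amplitude = 60,
                                wavelength = 1200, y_top = center_top(1200)))
  specs[[length(specs) + 1L]] <- list(
    name = "cosine_noisy",
    spec = synthetic_spine_spec(amplitude = 80, wavelength = 1200,
                                y_top = center_top(1200), noise_sd = 2,
                                seed = seed))
  lapply(specs, function(s) {
    fx <- generate_spine_mask(s$spec)
    list(name = s$name, spec = fx$spec, mask = fx$mask, truth = fx$truth)
  })
}
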