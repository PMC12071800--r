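# Curvature analysis: apex detection, curve typing, tilted-vertebra
# selection, Cobb angle, severity classification, and the end-to-end
# assessment pipeline.

#' Pipeline configuration
#'
#' @param grid_interval Spacing of the horizontal midpoint grid in pixels.
#'   The default of 50 px was chosen at the standard working height of
#'   2000 px so that successive grid lines fall within individual thoracic
#'   and lumbar vertebrae.
#' @param rescale_height Working image height in pixels; input masks are
#'   rescaled to this height before analysis (default 2000). Use `NA` to
#'   analyze the mask at its native resolution.
#' @param apex_threshold Minimum lateral displacement (px) for a local
#'   extremum to count as an apex candidate when deciding between simple
#'   and complex curvature; suppresses rasterization wiggle (default 20 px
#'   at the 2000 px working height).
#' @param severity_bounds Strictly increasing severity cut points in
#'   degrees, default `c(10, 20, 40)`.
#' @param min_midpoints Minimum number of grid midpoints (default 5).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_interval = 50, rescale_height = 2000,
                            apex_threshold = 20, severity_bounds = c(10, 20, 40),
                            min_midpoints = 5) {
  if (grid_interval < 1) st_config_error("grid_interval must be >= 1")
  if (!is.na(rescale_height) && rescale_height < 1)
    st_config_error("rescale_height must be >= 1 (or NA for native resolution)")
  if (length(severity_bounds) != 3L || any(diff(severity_bounds) <= 0))
    st_config_error("severity_bounds must be 3 strictly increasing values")
  if (min_midpoints < 4) st_config_error("min_midpoints must be >= 4")
  structure(list(grid_interval = grid_interval, rescale_height = rescale_height,
                 apex_threshold = apex_threshold, severity_bounds = severity_bounds,
                 min_midpoints = min_midpoints),
            class = "pipeline_config")
}

#' Detect curve apex(es) and classify the curvature as simple or complex
#'
#' The vertical reference line is drawn through the upper (first) midpoint,
#' `x = reference_x`. The lateral displacement `d(y) = x(y) - reference_x`
#' is sampled at every integer row between the upper and lower limits.
#' Local extrema of `|d|` reaching `apex_threshold` are apex candidates;
#' when candidates of both signs exist the curve is complex and the
#' largest-displacement candidate of each sign is returned (ordered by y),
#' otherwise the curve is simple and the single global maximum of `|d|`
#' is the apex (even if below threshold). Ties between distinct extrema are
#' broken by the smaller y; within a flat plateau of constant `|d|` the
#' central row represents the plateau, so a perfectly straight spine gets
#' an interior apex rather than its top endpoint.
#'
#' @param midline A `midline` with inclinations computed.
#' @param apex_threshold Displacement threshold in px (default 20).
#' @return A list with `apexes` (data frame `y`, `x`, `displacement`,
#'   displacement signed: negative = left of the reference line),
#'   `curve_type` (`"simple"` or `"complex"`), and `reference_x`.
#' @export
detect_apexes <- function(midline, apex_threshold = 20) {
  stopifnot(inherits(midline, "midline"))
  reference_x <- midline$midpoints$x_mid[1]
  ys <- midline$samples$y
  d <- midline$samples$x - reference_x
  ad <- abs(d)
  cand <- plateau_local_maxima(ad)
  apex_row <- function(i) data.frame(y = ys[i], x = midline$samples$x[i], displacement = d[i])
  strong <- cand[ad[cand] >= apex_threshold]
  signs <- sign(d[strong])
  if (length(strong) > 0L && any(signs > 0) && any(signs < 0)) {
    pick <- function(s) {
      set <- strong[signs == s]
      set[order(-ad[set], ys[set])][1]
    }
    ii <- sort(c(pick(1), pick(-1)))
    return(list(apexes = rbind(apex_row(ii[1]), apex_row(ii[2])),
                curve_type = "complex", reference_x = reference_x))
  }
  i <- cand[order(-ad[cand], ys[cand])][1]
  list(apexes = apex_row(i), curve_type = "simple", reference_x = reference_x)
}

# Indices of local maxima of a nonnegative series, plateau-aware: each run
# of equal values that is >= both neighbors is represented by its central
# index. Endpoint runs count (a monotone series peaks at an end).
plateau_local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    left_ok && right_ok
  }, logical(1))
  idx <- as.integer(floor((starts[is_max] + ends[is_max]) / 2))
  if (length(idx) == 0L) idx <- as.integer(floor((1 + length(v)) / 2))
  idx
}

#' Select the most tilted vertebrae around each apex
#'
#' For a simple curve, the upper tilted vertebra is the interior midpoint
#' with the greatest absolute inclination above the apex, and the lower one
#' the same below the apex. For a complex curve the midline is split
#' between the two apexes (at the integer row where the displacement
#' changes sign, or at the apexes' y-midpoint when it does not), and the
#' simple rule is applied within each segment. Ties on inclination are
#' broken by proximity in y to the apex, then by smaller y.
#'
#' @param midline A `midline` with inclinations computed.
#' @param apexes The result of [detect_apexes()].
#' @return A list of tilted pairs, each a list with `upper` and `lower`
#'   (single-row data frames of the selected midpoints). One pair for a
#'   simple curve (ordered upper curve first for a complex one).
#' @export
select_tilted_vertebrae <- function(midline, apexes) {
  stopifnot(inherits(midline, "midline"))
  mp <- midline$midpoints
  interior <- mp[!is.na(mp$inclination_deg), , drop = FALSE]
  pick_side <- function(cands, apex_y) {
    if (nrow(cands) == 0L)
      st_unmeasurable_curve_error(
        "no interior midpoint on one side of an apex; curve segment is unmeasurable")
    ord <- order(-abs(cands$inclination_deg), abs(cands$y - apex_y), cands$y)
    cands[ord[1], , drop = FALSE]
  }
  simple_pair <- function(seg, apex_y) {
    list(upper = pick_side(seg[seg$y < apex_y, , drop = FALSE], apex_y),
         lower = pick_side(seg[seg$y > apex_y, , drop = FALSE], apex_y))
  }
  if (apexes$curve_type == "simple") {
    return(list(simple_pair(interior, apexes$apexes$y[1])))
  }
  a1 <- apexes$apexes[1, ]; a2 <- apexes$apexes[2, ]
  seg_y <- midline$samples$y
  between <- seg_y > a1$y & seg_y < a2$y
  d <- midline$samples$x - apexes$reference_x
  split_y <- {
    yy <- seg_y[between]; dd <- d[between]
    cross <- which(diff(sign(dd)) != 0)
    if (length(cross) > 0L) {
      i <- cross[1]
      if (abs(dd[i]) <= abs(dd[i + 1])) yy[i] else yy[i + 1]
    } else {
      round((a1$y + a2$y) / 2)
    }
  }
  upper_seg <- interior[interior$y <= split_y, , drop = FALSE]
  lower_seg <- interior[interior$y >= split_y, , drop = FALSE]
  list(simple_pair(upper_seg, a1$y), simple_pair(lower_seg, a2$y))
}

#' Cobb angle from two endplate inclinations
#'
#' The Cobb angle is the angle between the endplate lines of the two most
#' tilted vertebrae (equivalently, between their perpendiculars at the
#' intersection point). With both inclinations measured from the
#' horizontal, that angle is simply `|theta_upper - theta_lower|`, which
#' also covers the parallel-line case where the intersection construction
#' degenerates.
#'
#' @param theta_upper,theta_lower Inclinations in degrees, each in
#'   (-90, 90).
#' @return The Cobb angle in degrees, in `[0, 180)`.
#' @export
cobb_angle <- function(theta_upper, theta_lower) {
  stopifnot(is.finite(theta_upper), is.finite(theta_lower),
            abs(theta_upper) < 90, abs(theta_lower) < 90)
  abs(theta_upper - theta_lower)
}

#' Classify scoliosis severity from a Cobb angle
#'
#' The clinical scale: below 10 degrees the curvature is a plain spinal
#' curve (no scoliosis); 10-20 mild; 20-40 moderate; above 40 severe.
#' Interval endpoints are lower-inclusive except "severe", which is
#' strictly above 40: the partition is `[0,10)`, `[10,20)`, `[20,40]`,
#' `(40, Inf)`.
#'
#' @param angle_deg A nonnegative Cobb angle in degrees.
#' @param bounds Severity cut points, default `c(10, 20, 40)`.
#' @return One of `"spinal curve"`, `"mild"`, `"moderate"`, `"severe"`.
#' @export
classify_severity <- function(angle_deg, bounds = c(10, 20, 40)) {
  stopifnot(length(angle_deg) == 1L, is.finite(angle_deg))
  if (angle_deg < 0) st_domain_error("Cobb angle must be nonnegative")
  if (angle_deg < bounds[1]) "spinal curve"
  else if (angle_deg < bounds[2]) "mild"
  else if (angle_deg <= bounds[3]) "moderate"
  else "severe"
}

#' Human-readable severity label
#'
#' @param severity A severity class from [classify_severity()].
#' @return The display label, e.g. `"Severe scoliosis"`.
#' @export
severity_label <- function(severity) {
  labels <- c("spinal curve" = "Spinal curve", "mild" = "Mild scoliosis",
              "moderate" = "Moderate scoliosis", "severe" = "Severe scoliosis")
  unname(labels[match.arg(severity, names(labels))])
}

#' Assess scoliosis from a binary spine mask
#'
#' Runs the full measurement pipeline: rescale to the working height,
#' select the spinal region, compute grid midpoints, fit the spline
#' midline, compute inclinations, detect apex(es), select the most tilted
#' vertebrae, and compute the Cobb angle(s) and severity. For a complex
#' (double) curve, two angles are reported (upper curve first) and the
#' severity is assigned from the larger one.
#'
#' @param mask A 0/1 matrix (foreground = spine).
#' @param config A [pipeline_config()].
#' @return An object of class `cobb_assessment`: a list with `measurement`
#'   (`curve_type`, `apexes`, `pairs`, `angles_deg`, `severity`,
#'   `severity_label`, `reference_x`), plus the intermediate `midline` and
#'   `region` for reporting, and the working-scale `mask`.
#' @examples
#' fx <- generate_spine_mask(synthetic_spine_spec(curve_form = "straight"))
#' a <- assess(fx$mask)
#' a$measurement$angles_deg  # ~0
#' @export
assess <- function(mask, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_mask(mask)
  if (sum(mask) == 0L) st_no_spine_error()
  if (!is.na(config$rescale_height))
    mask <- rescale_to_height(mask, config$rescale_height)
  region <- extract_spine_region(mask)
  mp <- compute_grid_midpoints(region, config$grid_interval, config$min_midpoints)
  midline <- compute_inclinations(fit_midline(mp))
  apexes <- detect_apexes(midline, config$apex_threshold)
  pairs <- select_tilted_vertebrae(midline, apexes)
  angles <- vapply(pairs, function(p)
    cobb_angle(p$upper$inclination_deg, p$lower$inclination_deg), numeric(1))
  severity <- classify_severity(max(angles), config$severity_bounds)
  structure(list(
    measurement = list(curve_type = apexes$curve_type,
                       apexes = apexes$apexes,
                       pairs = pairs,
                       angles_deg = angles,
                       severity = severity,
                       severity_label = severity_label(severity),
                       reference_x = apexes$reference_x),
    midline = midline, region = region, mask = mask, config = config),
    class = "cobb_assessment")
}

#' @export
print.cobb_assessment <- function(x, ...) {
  m <- x$measurement
  cat("Cobb assessment (", m$curve_type, " curve)\n", sep = "")
  cat("  angle(s): ", paste(sprintf("%.2f", m$angles_deg), collapse = ", "),
      " deg\n", sep = "")
  cat("  severity: ", m$severity_label, "\n", sep = "")
  cat("  apex row(s): ", paste(m$apexes$y, collapse = ", "), "\n", sep = "")
  invisible(x)
}
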