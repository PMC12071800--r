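# Report assembly: the structured ReportRow table, the annotated overlay
# image, configuration files, and the single-image measurement runner
# behind the command-line interface.

#' Build the structured report table from an assessment
#'
#' One `midpoint` row per grid midpoint (with its inclination where
#' defined), one `upper` and one `lower` row for the spine limits, one
#' `apex` row per apex (with its signed lateral displacement), one
#' `tilted` row per selected tilted vertebra, and one `result` row per
#' Cobb angle carrying the severity label.
#'
#' @param assessment A `cobb_assessment` from [assess()].
#' @return A data frame with the report columns (see [write_report_csv()]).
#' @export
report_rows <- function(assessment) {
  stopifnot(inherits(assessment, "cobb_assessment"))
  m <- assessment$measurement
  mp <- assessment$midline$midpoints
  blank <- function(record_type, n = 1L) data.frame(
    record_type = rep(record_type, n), index = NA_integer_, y_px = NA_real_,
    x_px = NA_real_, x_left_px = NA_real_, x_right_px = NA_real_,
    angle_deg = NA_real_, displacement_px = NA_real_, label = NA_character_)
  mid_rows <- blank("midpoint", nrow(mp))
  mid_rows$index <- seq_len(nrow(mp))
  mid_rows$y_px <- mp$y; mid_rows$x_px <- mp$x_mid
  mid_rows$x_left_px <- mp$x_left; mid_rows$x_right_px <- mp$x_right
  mid_rows$angle_deg <- mp$inclination_deg
  limit_row <- function(type, i) {
    r <- blank(type); r$y_px <- mp$y[i]; r$x_px <- mp$x_mid[i]
    r$x_left_px <- mp$x_left[i]; r$x_right_px <- mp$x_right[i]; r
  }
  apex_rows <- blank("apex", nrow(m$apexes))
  apex_rows$index <- seq_len(nrow(m$apexes))
  apex_rows$y_px <- m$apexes$y; apex_rows$x_px <- m$apexes$x
  apex_rows$displacement_px <- m$apexes$displacement
  tilted <- do.call(rbind, lapply(seq_along(m$pairs), function(i) {
    p <- m$pairs[[i]]
    do.call(rbind, lapply(list(p$upper, p$lower), function(v) {
      r <- blank("tilted"); r$index <- i
      r$y_px <- v$y; r$x_px <- v$x_mid
      r$x_left_px <- v$x_left; r$x_right_px <- v$x_right
      r$angle_deg <- v$inclination_deg; r
    }))
  }))
  results <- blank("result", length(m$angles_deg))
  results$index <- seq_along(m$angles_deg)
  results$angle_deg <- m$angles_deg
  results$label <- m$severity_label
  rbind(mid_rows, limit_row("upper", 1L), limit_row("lower", nrow(mp)),
        apex_rows, tilted, results)
}

# -- overlay rendering (best-effort; the CSV is the canonical output) ------

set_px <- function(img, y, x, rgb) {
  keep <- y >= 0 & y < dim(img)[1] & x >= 0 & x < dim(img)[2]
  y <- y[keep]; x <- x[keep]
  for (ch in 1:3) img[cbind(y + 1L, x + 1L, ch)] <- rgb[ch]
  img
}

draw_segment <- function(img, y0, x0, y1, x1, rgb) {
  len <- max(abs(y1 - y0), abs(x1 - x0), 1)
  t <- seq(0, 1, length.out = ceiling(len * 2) + 1)
  set_px(img, round(y0 + t * (y1 - y0)), round(x0 + t * (x1 - x0)), rgb)
}

draw_disc <- function(img, y, x, rgb, radius = 2L) {
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  set_px(img, round(y) + off$dy, round(x) + off$dx, rgb)
}

#' Render the annotated overlay image
#'
#' Draws, over the working-scale mask (or an optional background image of
#' the same size), the spinal contour, the grid midpoints, the spline
#' midline, the most tilted vertebrae as red lines, and their
#' perpendiculars in green. Rendering is best-effort and intended for
#' human review; the CSV report is the canonical output.
#'
#' @param assessment A `cobb_assessment` from [assess()].
#' @param background Optional greyscale matrix in `[0,1]` of the same size
#'   as the working mask (e.g. the rescaled radiograph); defaults to a
#'   dimmed rendering of the mask.
#' @return An RGB array (height x width x 3) in `[0,1]`.
#' @export
render_overlay <- function(assessment, background = NULL) {
  stopifnot(inherits(assessment, "cobb_assessment"))
  mask <- assessment$mask
  if (is.null(background)) background <- 0.35 * mask
  img <- array(rep(background, 3), dim = c(nrow(mask), ncol(mask), 3))
  contour <- assessment$region$contour
  img <- set_px(img, contour[, "y"], contour[, "x"], c(1, 1, 0))
  s <- assessment$midline$samples
  img <- set_px(img, s$y, round(s$x), c(1, 1, 1))
  mp <- assessment$midline$midpoints
  for (i in seq_len(nrow(mp)))
    img <- draw_disc(img, mp$y[i], mp$x_mid[i], c(0.2, 0.4, 1))
  for (a in seq_len(nrow(assessment$measurement$apexes))) {
    ap <- assessment$measurement$apexes[a, ]
    img <- draw_disc(img, ap$y, ap$x, c(1, 0.6, 0), radius = 3L)
  }
  for (p in assessment$measurement$pairs) {
    for (v in list(p$upper, p$lower)) {
      half <- (v$x_right - v$x_left) / 2
      phi <- v$inclination_deg * pi / 180
      # red: the tilted vertebra line (perpendicular to the midline tangent)
      img <- draw_segment(img,
                          v$y + half * sin(phi), v$x_mid - half * cos(phi),
                          v$y - half * sin(phi), v$x_mid + half * cos(phi),
                          c(1, 0, 0))
      # green: its perpendicular, used in the Cobb construction
      img <- draw_segment(img,
                          v$y - half * cos(phi), v$x_mid - half * sin(phi),
                          v$y + half * cos(phi), v$x_mid + half * sin(phi),
                          c(0, 1, 0))
    }
  }
  img
}

#' Load a pipeline configuration from a key = value file
#'
#' Recognized keys: `grid_interval`, `rescale_height`, `apex_threshold`,
#' `min_midpoints` (numbers) and `severity_bounds` (three comma-separated
#' numbers). Unspecified keys keep their defaults; unknown keys produce a
#' warning, not an error. Lines starting with `#` are comments.
#'
#' @param path Path to the configuration file, or `NULL` for all defaults.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- list(grid_interval = 50, rescale_height = 2000, apex_threshold = 20,
              severity_bounds = c(10, 20, 40), min_midpoints = 5)
  if (is.null(path)) return(do.call(pipeline_config, cfg))
  if (!file.exists(path)) st_io_error(sprintf("config file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      st_config_error(sprintf("cannot parse config line '%s'", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) {
      warning(sprintf("unknown config key '%s' ignored", key), call. = FALSE)
      next
    }
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    if (any(is.na(num)))
      st_config_error(sprintf("config key '%s' has non-numeric value '%s'", key, val))
    cfg[[key]] <- num
  }
  do.call(pipeline_config, cfg)
}

#' Measure one mask and write the report artifacts
#'
#' Runs [assess()] on a PNG mask (or on the first polygon of a VIA JSON
#' annotation file, rasterized into a `frame_height` x `frame_width`
#' frame), then writes the structured CSV report and the annotated
#' overlay PNG into `out_dir`. Each stage is logged to stderr with its
#' elapsed time.
#'
#' @param input_path Path to a PNG mask, or to a VIA 2.x JSON file.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param frame_height,frame_width Frame size for rasterizing a VIA
#'   polygon input; ignored for PNG input.
#' @param quiet Suppress stage logging (default `FALSE`).
#' @return A list of class `run_artifacts`: `input_path`, `config`,
#'   `measurement`, `report_rows`, `csv_path`, `overlay_path`, `log`.
#' @export
run_measure <- function(input_path, config = pipeline_config(), out_dir = ".",
                        frame_height = NULL, frame_width = NULL, quiet = FALSE) {
  log <- character(0)
  stage <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    line <- sprintf("[%s] %s (%.2fs)", format(Sys.time(), "%H:%M:%S"), label,
                    proc.time()[["elapsed"]] - t0)
    log <<- c(log, line)
    if (!quiet) message(line)
    value
  }
  mask <- stage("read input", {
    if (grepl("\\.json$", input_path, ignore.case = TRUE)) {
      if (is.null(frame_height) || is.null(frame_width))
        st_domain_error("VIA JSON input needs frame_height and frame_width")
      anns <- parse_via_annotations(paste(readLines(input_path, warn = FALSE),
                                          collapse = "\n"))
      if (length(anns) == 0L) st_no_spine_error("annotation file has no regions")
      polygon_to_mask(anns[[1]], frame_height, frame_width)
    } else {
      read_mask_png(input_path)
    }
  })
  assessment <- stage("assess curvature", assess(mask, config))
  rows <- report_rows(assessment)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  base <- sub("\\.[^.]+$", "", basename(input_path))
  csv_path <- file.path(out_dir, paste0(base, "_report.csv"))
  overlay_path <- file.path(out_dir, paste0(base, "_overlay.png"))
  stage("write report CSV", write_report_csv(rows, csv_path))
  stage("write overlay PNG",
        png::writePNG(render_overlay(assessment), target = overlay_path))
  m <- assessment$measurement
  if (!quiet)
    message(sprintf("Cobb angle(s): %s deg -> %s",
                    paste(sprintf("%.2f", m$angles_deg), collapse = ", "),
                    m$severity_label))
  structure(list(input_path = input_path, config = config,
                 measurement = m, report_rows = rows,
                 csv_path = csv_path, overlay_path = overlay_path, log = log),
            class = "run_artifacts")
}
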