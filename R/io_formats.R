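# Input/output: VIA polygon annotations, PNG masks, rescaling, report CSV.
#
# Conventions used throughout the package:
#   * masks are integer matrices (height x width) with values 0/1,
#     foreground = 1;
#   * pixel coordinates are 0-based, y = row index increasing downward,
#     x = column index increasing rightward; the center of pixel (y, x)
#     is the point (x, y);
#   * all angles are in degrees.

validate_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || nrow(mask) < 1L || ncol(mask) < 1L)
    st_domain_error(sprintf("%s must be a matrix with at least one row and column", arg))
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1)))
    st_domain_error(sprintf("%s must contain only 0/1 values", arg))
  invisible(mask)
}

#' Parse VGG Image Annotator (VIA 2.x) polygon annotations
#'
#' Reads a VIA 2.x project (or annotation) JSON export and returns the spine
#' boundary polygons it contains. Both `polygon` and `polyline` region shapes
#' are accepted; any other shape is an error, since this package only
#' understands closed spine contours.
#'
#' @param json_text A single string with the JSON content (not a file path).
#' @return A list of annotations. Each element is a list with `image_id`
#'   (the image filename) and `vertices`, an n x 2 matrix with columns
#'   `x` and `y` in pixel coordinates, vertex order as annotated.
#'   Images with zero regions contribute no elements.
#' @examples
#' txt <- '{"img1.png":{"filename":"img1.png","regions":[{"shape_attributes":
#'   {"name":"polygon","all_points_x":[1,4,4,1],"all_points_y":[1,1,3,3]}}]}}'
#' parse_via_annotations(txt)
#' @export
parse_via_annotations <- function(json_text) {
  stopifnot(is.character(json_text), length(json_text) == 1L)
  doc <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) st_format_error(paste0("malformed VIA JSON: ", conditionMessage(e)))
  )
  # A full project export keeps image metadata under "_via_img_metadata";
  # the plain annotation export is that map directly.
  meta <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]] else doc
  out <- list()
  for (key in names(meta)) {
    entry <- meta[[key]]
    if (!is.list(entry) || is.null(entry$regions)) next
    image_id <- if (!is.null(entry$filename)) entry$filename else key
    for (region in entry$regions) {
      sa <- region$shape_attributes
      if (is.null(sa) || is.null(sa$name))
        st_format_error("region without shape_attributes$name")
      if (!sa$name %in% c("polygon", "polyline"))
        st_format_error(sprintf("unsupported region shape '%s' (only polygon/polyline)", sa$name))
      xs <- as.numeric(unlist(sa$all_points_x))
      ys <- as.numeric(unlist(sa$all_points_y))
      if (length(xs) != length(ys))
        st_format_error(sprintf(
          "coordinate arrays of unequal length (%d x vs %d y) in image '%s'",
          length(xs), length(ys), image_id))
      if (length(xs) == 0L || any(!is.finite(xs)) || any(!is.finite(ys)) ||
          any(xs < 0) || any(ys < 0))
        st_format_error(sprintf("invalid polygon coordinates in image '%s'", image_id))
      out[[length(out) + 1L]] <- structure(
        list(image_id = image_id,
             vertices = cbind(x = xs, y = ys)),
        class = "polygon_annotation")
    }
  }
  out
}

#' Rasterize a polygon annotation to a binary mask
#'
#' A pixel belongs to the foreground when its center lies inside the polygon
#' or exactly on its boundary (even-odd fill rule for self-intersecting
#' polygons). Pixel centers sit at integer coordinates, so a rectangle with
#' corners (1,1) and (4,3) covers pixel columns 1..4 and rows 1..3.
#'
#' @param poly An annotation from [parse_via_annotations()], or any list with
#'   a `vertices` matrix (columns x, y).
#' @param height,width Output mask dimensions in pixels.
#' @return An integer `height` x `width` matrix of 0/1.
#' @export
polygon_to_mask <- function(poly, height, width) {
  stopifnot(height >= 1, width >= 1)
  v <- poly$vertices
  if (is.null(v) || nrow(v) < 3L)
    st_domain_error("degenerate polygon: fewer than 3 vertices")
  if (any(v[, 1] < 0 | v[, 1] > width | v[, 2] < 0 | v[, 2] > height))
    st_geometry_error(sprintf(
      "polygon vertex outside the %dx%d frame", height, width))
  mask <- matrix(0L, nrow = height, ncol = width)
  # Only the polygon's bounding box can contain foreground pixels.
  c0 <- max(0L, floor(min(v[, 1]))); c1 <- min(width - 1L, ceiling(max(v[, 1])))
  r0 <- max(0L, floor(min(v[, 2]))); r1 <- min(height - 1L, ceiling(max(v[, 2])))
  if (c1 < c0 || r1 < r0) return(mask)
  grid <- expand.grid(x = c0:c1, y = r0:r1)
  inside <- pracma::inpolygon(grid$x, grid$y, v[, 1], v[, 2], boundary = TRUE)
  # inpolygon can miss centers lying exactly on slanted edges; the
  # boundary-inclusive rule demands them, so test edge membership directly
  border <- points_on_polygon_boundary(grid$x, grid$y, v)
  mask[cbind(grid$y + 1L, grid$x + 1L)] <- as.integer(inside | border)
  mask
}

points_on_polygon_boundary <- function(px, py, v, tol = 1e-9) {
  hit <- rep(FALSE, length(px))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    scale <- max(abs(c(x1, y1, x2, y2)), 1)
    on_line <- abs(cross) <= tol * scale
    in_box <- px >= min(x1, x2) - tol & px <= max(x1, x2) + tol &
      py >= min(y1, y2) - tol & py <= max(y1, y2) + tol
    hit <- hit | (on_line & in_box)
  }
  hit
}

#' Rescale a binary mask to a target height
#'
#' Nearest-neighbor resampling, which preserves binarity exactly. The output
#' width is `round(width * target_height / height)` (at least 1), so the
#' aspect ratio is preserved up to rounding. When `target_height` equals the
#' mask height the input is returned unchanged. The pipeline default target
#' of 2000 px standardizes the scale at which the midpoint grid operates.
#'
#' @param mask A 0/1 matrix.
#' @param target_height Output height in pixels (>= 1).
#' @return A 0/1 matrix with `target_height` rows.
#' @export
rescale_to_height <- function(mask, target_height) {
  validate_mask(mask)
  stopifnot(target_height >= 1)
  h <- nrow(mask); w <- ncol(mask)
  if (target_height == h) return(mask)
  new_w <- max(1L, as.integer(round(w * target_height / h)))
  src_r <- pmin(h, pmax(1L, floor((seq_len(target_height) - 0.5) * h / target_height) + 1L))
  src_c <- pmin(w, pmax(1L, floor((seq_len(new_w) - 0.5) * w / new_w) + 1L))
  mask[src_r, src_c, drop = FALSE]
}

#' Read a binary mask from an 8-bit PNG
#'
#' Greyscale values are binarized at a luminance of 128/255: foreground iff
#' luminance >= 128. RGB images are collapsed with the standard luminance
#' weights 0.299 R + 0.587 G + 0.114 B first; an alpha channel is ignored.
#'
#' @param path Path to a PNG file.
#' @return An integer 0/1 matrix (height x width).
#' @export
read_mask_png <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    st_io_error(sprintf("cannot read mask: file '%s' does not exist", path))
  img <- tryCatch(png::readPNG(path),
                  error = function(e) st_format_error(
                    sprintf("'%s' is not a readable PNG: %s", path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3] >= 3L) {
      lum <- 0.299 * img[, , 1, drop = TRUE] + 0.587 * img[, , 2, drop = TRUE] +
        0.114 * img[, , 3, drop = TRUE]
    } else {
      lum <- img[, , 1, drop = TRUE]
    }
  } else {
    lum <- img
  }
  # 1e-9 guards against the luminance weights not summing to 1 exactly in
  # floating point; the data are 8-bit so true values are multiples of 1/255.
  matrix(as.integer(lum * 255 >= 128 - 1e-9), nrow = d[1])
}

#' Write a binary mask as an 8-bit grey PNG
#'
#' Foreground pixels are written as 255, background as 0, so
#' `read_mask_png(write_mask_png(m, path))` is the identity.
#'
#' @param mask A 0/1 matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask)
  ok <- tryCatch({
    png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) st_io_error(sprintf("cannot write PNG to '%s'", path))
  invisible(path)
}

report_columns <- c("record_type", "index", "y_px", "x_px", "x_left_px",
                    "x_right_px", "angle_deg", "displacement_px", "label")

#' Write the structured measurement report as CSV
#'
#' The report is a long table with one row per recorded item: the grid
#' midpoints, the upper/lower spine limits, the apex(es), the most tilted
#' vertebrae, and one `result` row per Cobb angle with the severity label.
#' Unpopulated fields are left blank; numeric fields are printed with at
#' most 4 decimal places.
#'
#' @param rows A data frame with columns `record_type, index, y_px, x_px,
#'   x_left_px, x_right_px, angle_deg, displacement_px, label` (missing
#'   columns are added blank).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [report_rows()] to build the table from an assessment.
#' @export
write_report_csv <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    st_domain_error("report rows must be a non-empty data frame")
  for (col in report_columns) if (is.null(rows[[col]])) rows[[col]] <- NA
  rows <- rows[report_columns]
  fmt <- function(x) {
    if (is.numeric(x)) x <- round(x, 4)
    out <- as.character(x)
    out[is.na(out)] <- ""
    out
  }
  txt <- vapply(rows, fmt, character(nrow(rows)))
  if (nrow(rows) == 1L) txt <- matrix(txt, nrow = 1L)
  lines <- c(paste(report_columns, collapse = ","),
             apply(txt, 1L, paste, collapse = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) st_io_error(sprintf("cannot write report CSV to '%s'", path))
  invisible(path)
}

#' Read back a report CSV written by [write_report_csv()]
#'
#' @param path Path to the CSV file.
#' @return A data frame with the report columns; blank cells become `NA`.
#' @export
read_report_csv <- function(path) {
  if (!file.exists(path)) st_io_error(sprintf("report '%s' does not exist", path))
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(record_type = "character", label = "character"))
}
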