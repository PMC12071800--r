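# Midline reconstruction: largest connected component, grid-row midpoints,
# interpolating spline, per-midpoint inclination angles.

#' Select the spinal region of a binary mask
#'
#' The 8-connected foreground component with the largest pixel area is taken
#' to be the spine (the segmentation network may emit spurious small blobs).
#' Ties are broken by the component whose topmost-then-leftmost pixel comes
#' first in raster order.
#'
#' @param mask A 0/1 matrix with at least one foreground pixel.
#' @return An object of class `spine_region`: a list with `mask` (the
#'   selected component in the original frame), `contour` (n x 2 matrix of
#'   0-based `y`, `x` boundary coordinates, ordered and closed), and
#'   `area_px`.
#' @export
extract_spine_region <- function(mask) {
  validate_mask(mask)
  if (sum(mask) == 0L) st_no_spine_error()
  labels <- label_components_8(mask)
  areas <- tabulate(labels[labels > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # topmost-then-leftmost component pixel decides the tie
    keys <- vapply(best, function(lb) {
      idx <- which(labels == lb, arr.ind = TRUE)
      top <- min(idx[, 1])
      left <- min(idx[idx[, 1] == top, 2])
      (top - 1) * (ncol(mask) + 1) + left
    }, numeric(1))
    best <- best[which.min(keys)]
  }
  comp <- matrix(as.integer(labels == best), nrow = nrow(mask))
  oc <- EBImage::ocontour(EBImage::Image(t(comp)))[[1]]
  contour <- cbind(y = oc[, 2], x = oc[, 1])  # ocontour returns 0-based (x, y)
  structure(list(mask = comp, contour = contour, area_px = sum(comp)),
            class = "spine_region")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged afterwards with a small union-find pass.
label_components_8 <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  diag_pairs <- unique(diag_pairs[diag_pairs[, 1] > 0 & diag_pairs[, 2] > 0 &
                                  diag_pairs[, 1] != diag_pairs[, 2], , drop = FALSE])
  for (i in seq_len(nrow(diag_pairs))) union(diag_pairs[i, 1], diag_pairs[i, 2])
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Compute grid-row midpoints of a spine region
#'
#' Horizontal grid lines are placed every `grid_interval` rows starting at
#' the region's topmost foreground row; the bottommost foreground row is
#' appended if it is not already a grid row. At each grid row, the leftmost
#' and rightmost foreground columns of the region are the two boundary
#' crossings, and their mean is the midpoint. The first and last midpoints
#' mark the upper and lower limits of the spine. Anchoring the grid at the
#' region (not the image) makes the result invariant to translation.
#'
#' @param region A `spine_region` from [extract_spine_region()].
#' @param grid_interval Spacing of grid rows in pixels (default 50 at the
#'   standard working height of 2000 px).
#' @param min_midpoints Minimum number of midpoints needed downstream
#'   (default 5, which guarantees at least 3 interior inclinations).
#' @return A data frame with columns `y`, `x_left`, `x_right`, `x_mid`
#'   (0-based pixel coordinates, sorted by `y`) and `inclination_deg`
#'   (filled later by [compute_inclinations()]).
#' @export
compute_grid_midpoints <- function(region, grid_interval = 50, min_midpoints = 5) {
  stopifnot(inherits(region, "spine_region"), grid_interval >= 1)
  mask <- region$mask
  occupied <- which(rowSums(mask) > 0L)  # 1-based rows
  y_top <- min(occupied) - 1L
  y_bot <- max(occupied) - 1L
  ys <- seq(y_top, y_bot, by = grid_interval)
  if (ys[length(ys)] != y_bot) ys <- c(ys, y_bot)
  rows <- lapply(ys, function(y) {
    cols <- which(mask[y + 1L, ] > 0L)
    if (length(cols) == 0L) return(NULL)  # possible only for exotic components
    data.frame(y = y, x_left = min(cols) - 1L, x_right = max(cols) - 1L)
  })
  mp <- do.call(rbind, rows)
  if (is.null(mp) || nrow(mp) < min_midpoints)
    st_insufficient_midpoints_error(sprintf(
      "only %d grid midpoints found (need %d); try a smaller grid_interval",
      if (is.null(mp)) 0L else nrow(mp), min_midpoints))
  mp$x_mid <- (mp$x_left + mp$x_right) / 2
  mp$inclination_deg <- NA_real_
  mp[order(mp$y), , drop = FALSE]
}

#' Fit the spinal midline through the grid midpoints
#'
#' A cubic interpolating spline x(y) is fit through the (y, x_mid) pairs,
#' smoothing the path between midpoints while passing through every
#' midpoint exactly. End conditions follow Forsythe-Malcolm-Moler (the
#' spline near each end is the exact cubic through the four nearest
#' midpoints), which reproduces polynomial midlines up to degree 3
#' exactly and avoids the boundary layer a natural (zero end curvature)
#' spline leaves on curved spines.
#'
#' @param midpoints Data frame from [compute_grid_midpoints()] with at
#'   least 4 midpoints and strictly increasing `y`.
#' @return An object of class `midline`: a list with `midpoints`, `spline`
#'   (a function x(y) also accepting `deriv`), and `samples` (a data frame
#'   of x evaluated at every integer row spanned by the midpoints).
#' @export
fit_midline <- function(midpoints) {
  stopifnot(is.data.frame(midpoints))
  if (nrow(midpoints) < 4L)
    st_domain_error("at least 4 midpoints are required to fit the midline")
  y <- midpoints$y
  if (anyDuplicated(y) || is.unsorted(y, strictly = TRUE))
    st_domain_error("midpoint y values must be strictly increasing (no duplicates)")
  f <- stats::splinefun(y, midpoints$x_mid, method = "fmm")
  ys <- seq(min(y), max(y))
  structure(list(midpoints = midpoints,
                 spline = f,
                 samples = data.frame(y = ys, x = f(ys))),
            class = "midline")
}

#' Compute vertebral inclination angles along the midline
#'
#' At each interior midpoint the line perpendicular to the midline tangent
#' stands in for the vertebral endplate; its angle to the horizontal equals
#' the tangent's angle to the vertical, namely `atan(dx/dy)` (the spline's
#' analytic derivative). The angle is signed: positive when the midline
#' moves rightward as y increases. The first and last midpoints (the upper
#' and lower spine limits) get no inclination.
#'
#' @param midline A `midline` from [fit_midline()].
#' @return The same `midline` with `midpoints$inclination_deg` filled for
#'   interior midpoints.
#' @export
compute_inclinations <- function(midline) {
  stopifnot(inherits(midline, "midline"))
  mp <- midline$midpoints
  n <- nrow(mp)
  interior <- seq_len(n)[-c(1L, n)]
  mp$inclination_deg[interior] <-
    atan(midline$spline(mp$y[interior], deriv = 1)) * 180 / pi
  midline$midpoints <- mp
  midline
}
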