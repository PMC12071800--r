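# Segmentation evaluation: per-pair pixel-overlap metrics, single-instance
# average precision over IoU thresholds, and aggregation to means.

#' Pixel-overlap metrics for one predicted/ground-truth mask pair
#'
#' Computes the confusion counts and the derived overlap metrics:
#' IoU = tp/(tp+fp+fn), DSC = 2tp/(2tp+fp+fn), precision = tp/(tp+fp)
#' (defined as 0 for an empty prediction), recall = tp/(tp+fn),
#' over-segmentation = 1 - precision (predicted area outside the target),
#' under-segmentation = 1 - recall (target area missed).
#'
#' @param pred,gt 0/1 matrices of identical dimensions; `gt` must have at
#'   least one foreground pixel.
#' @return A one-row data frame with columns `tp, fp, fn, iou, dsc,
#'   precision, recall, over_seg, under_seg`.
#' @export
pair_metrics <- function(pred, gt) {
  validate_mask(pred, "pred"); validate_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    st_stop("spinetrace_shape_error", sprintf(
      "mask dimensions differ: %dx%d vs %dx%d",
      nrow(pred), ncol(pred), nrow(gt), ncol(gt)))
  if (sum(gt) == 0L)
    st_domain_error("ground-truth mask has no foreground pixels")
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  data.frame(tp = tp, fp = fp, fn = fn,
             iou = tp / (tp + fp + fn),
             dsc = 2 * tp / (2 * tp + fp + fn),
             precision = precision, recall = recall,
             over_seg = 1 - precision, under_seg = 1 - recall)
}

#' Average precision over IoU thresholds 0.50:0.05:0.95
#'
#' COCO-style AP restricted to a single class with one ground-truth
#' instance and one scored detection per image. For each IoU threshold t,
#' detections are sorted by descending score and counted as true positives
#' when their IoU with the image's ground truth reaches t (each ground
#' truth matchable once); AP_t is the area under the precision-recall
#' curve by all-point interpolation, and the returned AP is the mean of
#' AP_t over the 10 thresholds. For a single image this reduces to
#' (number of thresholds passed)/10.
#'
#' @param pairs A list; each element a list with `pred` (0/1 matrix),
#'   `score` (detection confidence in `[0,1]`), and `gt` (0/1 matrix).
#' @param iou_thresholds IoU acceptance thresholds,
#'   default `seq(0.5, 0.95, by = 0.05)`.
#' @return The average precision, a fraction in `[0,1]`.
#' @export
average_precision <- function(pairs, iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (!is.list(pairs) || length(pairs) == 0L)
    st_domain_error("average_precision needs at least one (pred, score, gt) pair")
  ious <- vapply(pairs, function(p) pair_metrics(p$pred, p$gt)$iou, numeric(1))
  scores <- vapply(pairs, function(p) as.numeric(p$score), numeric(1))
  if (any(scores < 0 | scores > 1)) st_domain_error("scores must lie in [0,1]")
  n_gt <- length(pairs)
  ord <- order(-scores)
  ap_at <- vapply(iou_thresholds, function(t) {
    tp <- as.integer(ious[ord] >= t)
    cum_tp <- cumsum(tp)
    recall <- cum_tp / n_gt
    precision <- cum_tp / seq_along(tp)
    # all-point interpolation: precision envelope from the right
    p_env <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * p_env)
  }, numeric(1))
  mean(ap_at)
}

#' Aggregate per-pair segmentation metrics
#'
#' Unweighted arithmetic means of the per-pair metrics, with the AP value
#' passed through. Note that means of ratios do not commute: the aggregate
#' DSC is the mean of per-pair DSCs and does not in general equal
#' `2*m_iou/(1+m_iou)`; the complement identities
#' `mean_precision + mean_over_seg = 1` and
#' `mean_recall + mean_under_seg = 1` do survive averaging.
#'
#' @param evals A data frame of per-pair rows from [pair_metrics()]
#'   (or a list of such rows), with at least one row.
#' @param ap The average precision for the same set, from
#'   [average_precision()] (default `NA`).
#' @return A one-row data frame with `m_iou, m_dsc, m_ap, mean_precision,
#'   mean_recall, mean_over_seg, mean_under_seg, n_pairs`.
#' @export
aggregate_seg_metrics <- function(evals, ap = NA_real_) {
  if (is.list(evals) && !is.data.frame(evals)) evals <- do.call(rbind, evals)
  if (!is.data.frame(evals) || nrow(evals) == 0L)
    st_domain_error("aggregate_seg_metrics needs at least one per-pair evaluation")
  data.frame(m_iou = mean(evals$iou), m_dsc = mean(evals$dsc), m_ap = ap,
             mean_precision = mean(evals$precision),
             mean_recall = mean(evals$recall),
             mean_over_seg = mean(evals$over_seg),
             mean_under_seg = mean(evals$under_seg),
             n_pairs = nrow(evals))
}

#' Evaluate two directories of same-named mask PNGs
#'
#' Pairs each PNG in `pred_dir` with the same-named PNG in `gt_dir`,
#' computes per-pair metrics and the single-instance AP (scores from
#' `scores` when given, else 1 for every detection), and aggregates.
#'
#' @param pred_dir,gt_dir Directories of predicted / ground-truth masks.
#' @param scores Optional data frame with columns `image` (file name) and
#'   `score` in `[0,1]`.
#' @return A list with `per_pair` (data frame, one row per image, with an
#'   `image` column) and `aggregate` (from [aggregate_seg_metrics()]).
#' @export
evaluate_mask_dirs <- function(pred_dir, gt_dir, scores = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.png$", ignore.case = TRUE))
  if (length(preds) == 0L) st_io_error(sprintf("no PNG masks in '%s'", pred_dir))
  missing <- preds[!file.exists(file.path(gt_dir, preds))]
  if (length(missing) > 0L)
    st_io_error(sprintf("ground-truth mask missing for: %s",
                        paste(missing, collapse = ", ")))
  pairs <- lapply(preds, function(f) {
    s <- 1
    if (!is.null(scores)) {
      hit <- match(f, scores$image)
      if (!is.na(hit)) s <- scores$score[hit]
    }
    list(pred = read_mask_png(file.path(pred_dir, f)), score = s,
         gt = read_mask_png(file.path(gt_dir, f)))
  })
  per_pair <- do.call(rbind, lapply(pairs, function(p) pair_metrics(p$pred, p$gt)))
  per_pair <- cbind(image = preds, per_pair)
  list(per_pair = per_pair,
       aggregate = aggregate_seg_metrics(per_pair, average_precision(pairs)))
}
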