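# Two-level agreement evaluation of a predicted capillary mask against
# ground truth: six pixel-level confusion metrics, the region-level TP/FN/FP
# scheme suited to thin structures (a ground-truth region counts as detected
# if any of its pixels are predicted), and Bland-Altman agreement of the
# derived capillary variables. Undefined ratios (0/0) are reported as NA,
# never coerced to 0.

#' Pixel-level confusion counts
#'
#' Per-pixel cross-tabulation of two binary masks on the same grid, with
#' foreground (255) as the positive class.
#'
#' @param pred,gt H x W matrices with values in {0, 255}.
#' @return a `confusion_counts` list: `tp`, `tn`, `fp`, `fn` (they always
#'   sum to the number of pixels).
#' @export
pixel_confusion <- function(pred, gt) {
  assert_binary_mask(pred, "pred")
  assert_binary_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stop(sprintf("mask grids differ: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(gt), collapse = "x")))
  p <- pred > 0; g <- gt > 0
  structure(list(
    tp = sum(p & g), tn = sum(!p & !g),
    fp = sum(p & !g), fn = sum(!p & g)
  ), class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Pixel-level metrics from confusion counts
#'
#' Accuracy, precision, recall, specificity, Sorensen-Dice and IoU. Any 0/0
#' is `NA`. Whenever Dice and IoU are both defined they satisfy
#' `iou = dice / (2 - dice)`.
#'
#' @param counts a [pixel_confusion()] result (or any list with tp/tn/fp/fn).
#' @return a `pixel_metric_report` list with the six metrics in `[0, 1]`.
#' @export
pixel_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty grid")
  structure(list(
    accuracy = (tp + tn) / n,
    precision = safe_ratio(tp, tp + fp),
    recall = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    dice = safe_ratio(2 * tp, 2 * tp + fp + fn),
    iou = safe_ratio(tp, tp + fp + fn)
  ), class = "pixel_metric_report")
}

#' Region-level confusion and metrics
#'
#' Ground-truth and predicted masks are labeled independently. A
#' ground-truth region overlapping at least one predicted-foreground pixel
#' is a TP region; one with no overlap is FN. A predicted region with no
#' overlap with ground-truth foreground is FP. Note the mixed units: TP and
#' FN are counted in ground-truth regions, FP in predicted regions, so one
#' predicted blob touching several ground-truth regions credits each of
#' them. Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' dice = 2TP/(2TP+FP+FN); 0/0 is `NA`. There are deliberately no TN or IoU
#' fields at region level (no meaningful region unit for true negatives).
#'
#' @param pred,gt H x W matrices with values in {0, 255}.
#' @param connectivity 4 or 8 (default 8), for both labelings.
#' @return a `region_metric_report` list: `tp_regions`, `fn_regions`,
#'   `fp_regions`, `precision`, `recall`, `dice`.
#' @export
region_confusion <- function(pred, gt, connectivity = 8) {
  assert_binary_mask(pred, "pred")
  assert_binary_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stop(sprintf("mask grids differ: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(gt), collapse = "x")))
  storage.mode(pred) <- "integer"; storage.mode(gt) <- "integer"
  lg <- cpp_label_cc(gt, as.integer(connectivity))
  lp <- cpp_label_cc(pred, as.integer(connectivity))
  ng <- max(lg); np <- max(lp)
  gt_hit <- if (ng > 0) tabulate(lg[lg > 0 & pred > 0], nbins = ng) > 0 else logical(0)
  pr_hit <- if (np > 0) tabulate(lp[lp > 0 & gt > 0], nbins = np) > 0 else logical(0)
  tp <- sum(gt_hit); fn <- ng - tp; fp <- np - sum(pr_hit)
  structure(list(
    tp_regions = tp, fn_regions = fn, fp_regions = fp,
    precision = safe_ratio(tp, tp + fp),
    recall = safe_ratio(tp, tp + fn),
    dice = safe_ratio(2 * tp, 2 * tp + fp + fn)
  ), class = "region_metric_report")
}

#' Evaluate a set of predicted masks against ground truth
#'
#' Per-image pixel- and region-level metrics plus their equal-weight means
#' across images (per-image averaging, not pooled counts).
#'
#' @param preds,gts lists of binary masks, pairwise on the same grids.
#' @param connectivity 4 or 8 for the region level.
#' @return list with `per_image` (tibble, one row per image) and `mean`
#'   (named numeric, `NA`s removed per metric).
#' @export
evaluate_masks <- function(preds, gts, connectivity = 8) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    pm <- pixel_metrics(pixel_confusion(preds[[i]], gts[[i]]))
    rm <- region_confusion(preds[[i]], gts[[i]], connectivity)
    tibble::tibble(image = i,
                   accuracy = pm$accuracy, precision = pm$precision,
                   recall = pm$recall, specificity = pm$specificity,
                   dice = pm$dice, iou = pm$iou,
                   region_tp = rm$tp_regions, region_fn = rm$fn_regions,
                   region_fp = rm$fp_regions,
                   region_precision = rm$precision,
                   region_recall = rm$recall, region_dice = rm$dice)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), "image")
  means <- vapply(per_image[metric_cols],
                  function(v) mean(v, na.rm = TRUE), numeric(1))
  list(per_image = per_image, mean = means)
}

#' Bland-Altman agreement analysis
#'
#' Differences between paired measurements under the chosen sign convention
#' (default prediction minus ground truth), their mean and sample standard
#' deviation (n - 1), and the 95% limits of agreement
#' `mean_diff +/- 1.96 * sd_diff`. Per-pair plotting coordinates
#' (pair mean, difference) are included.
#'
#' @param gt,pred paired measurements, equal length, n >= 2.
#' @param sign "pred_minus_gt" (default) or "gt_minus_pred".
#' @return a `bland_altman_result`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `sign_convention`, and `points` (tibble: mean, diff).
#' @export
bland_altman <- function(gt, pred, sign = c("pred_minus_gt", "gt_minus_pred")) {
  sign <- match.arg(sign)
  if (length(gt) != length(pred)) stop("gt and pred lengths differ")
  if (length(gt) < 2) stop("need at least 2 pairs")
  d <- if (sign == "pred_minus_gt") pred - gt else gt - pred
  m <- mean(d); s <- sd(d)
  structure(list(
    mean_diff = m, sd_diff = s,
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
    n = length(d), sign_convention = sign,
    points = tibble::tibble(mean = (gt + pred) / 2, diff = d)
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d (%s): mean diff %.4g, LoA [%.4g, %.4g]\n",
              x$n, x$sign_convention, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param object a `bland_altman_result`.
#' @param ... unused.
#' @return a ggplot: pair means vs differences with the mean-difference and
#'   limit-of-agreement lines.
#' @export
autoplot.bland_altman_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$mean_diff, color = "red",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        color = "blue", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean of pair", y = object$sign_convention)
}
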