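# Binary mask -> capillary variables: connected-component blob analysis,
# number / total area / average area, and the through-origin calibration
# that maps automated counts onto manual-annotation scale.

#' Label connected foreground regions of a binary mask
#'
#' Maximal connected components of the {0, 255} foreground under 4- or
#' 8-connectivity (default 8, so thin diagonal vessels stay single regions).
#' Labels are deterministic: contiguous from 1 in raster-scan order of each
#' region's first-encountered pixel. Components smaller than `min_region_px`
#' are discarded (none by default) and the remaining regions relabeled.
#'
#' @param mask H x W matrix with values in {0, 255}.
#' @param connectivity 4 or 8 (default 8).
#' @param min_region_px minimum pixel area to keep a region (default 0).
#' @return a `region_table` tibble with columns `label`, `area_px`,
#'   `bbox_x`, `bbox_y`, `bbox_w`, `bbox_h` (0-based x/y of the bounding
#'   box), `cx`, `cy` (0-based centroid), plus attributes `connectivity`
#'   and `min_region_px`.
#' @export
label_regions <- function(mask, connectivity = 8, min_region_px = 0) {
  assert_binary_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "integer"
  lab <- cpp_label_cc(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) {
    tab <- tibble::tibble(label = integer(), area_px = integer(),
                          bbox_x = integer(), bbox_y = integer(),
                          bbox_w = integer(), bbox_h = integer(),
                          cx = numeric(), cy = numeric())
  } else {
    fg <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[fg]
    x0 <- fg[, 2] - 1L   # 0-based
    y0 <- fg[, 1] - 1L
    area <- tabulate(lv, nbins = n)
    xmin <- tapply(x0, lv, min); xmax <- tapply(x0, lv, max)
    ymin <- tapply(y0, lv, min); ymax <- tapply(y0, lv, max)
    tab <- tibble::tibble(
      label = seq_len(n),
      area_px = as.integer(area),
      bbox_x = as.integer(xmin), bbox_y = as.integer(ymin),
      bbox_w = as.integer(xmax - xmin + 1L),
      bbox_h = as.integer(ymax - ymin + 1L),
      cx = as.numeric(tapply(x0, lv, mean)),
      cy = as.numeric(tapply(y0, lv, mean))
    )
    if (min_region_px > 0) {
      tab <- tab[tab$area_px >= min_region_px, , drop = FALSE]
      tab$label <- seq_len(nrow(tab))
    }
  }
  attr(tab, "connectivity") <- as.integer(connectivity)
  attr(tab, "min_region_px") <- as.integer(min_region_px)
  class(tab) <- c("region_table", class(tab))
  tab
}

#' Capillary variables from a region table
#'
#' The three quantities used to characterize a capillary field: number of
#' regions, total area, and average area (total / number; `NA` when there
#' are no regions). When the pixel pitch is supplied, physical areas in
#' square micrometres (`area_px * um_per_px^2`) are appended.
#'
#' @param table a [label_regions()] result.
#' @param um_per_px optional pixel pitch in micrometres.
#' @return a `capillary_variables` list: `number`, `total_area_px`,
#'   `average_area_px`, and, if `um_per_px` is given, `total_area_um2` and
#'   `average_area_um2`.
#' @export
capillary_variables <- function(table, um_per_px = NULL) {
  number <- nrow(table)
  total <- as.integer(sum(table$area_px))
  avg <- if (number > 0) total / number else NA_real_
  out <- list(number = number, total_area_px = total, average_area_px = avg)
  if (!is.null(um_per_px)) {
    out$total_area_um2 <- total * um_per_px^2
    out$average_area_um2 <- if (number > 0) avg * um_per_px^2 else NA_real_
  }
  structure(out, class = "capillary_variables")
}

#' @export
print.capillary_variables <- function(x, ...) {
  cat(sprintf("<capillary_variables> number %d, total area %d px, average area %s px\n",
              x$number, x$total_area_px,
              ifelse(is.na(x$average_area_px), "NA",
                     format(x$average_area_px, digits = 5))))
  invisible(x)
}

#' @export
as.data.frame.capillary_variables <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Fit a through-origin calibration regression
#'
#' Automated detection systematically over- or under-counts relative to
#' manual annotation; a through-origin least-squares fit `y = b x` (detected
#' on annotated) captures that scale factor per variable. The slope is
#' `sum(x*y) / sum(x^2)` (equivalently `lm(y ~ 0 + x)`), and `r` is the
#' Pearson correlation of the pairs.
#'
#' @param x_manual manually annotated values (regressor).
#' @param y_detected automatically detected values (response).
#' @param variable_name one of "number", "total_area", "average_area" (or
#'   any label).
#' @param intercept fit an intercept as well (off by default; the
#'   through-origin form is the calibration contract).
#' @return a `calibration_model`: `slope`, `r`, `variable_name`,
#'   `intercept` (0 unless requested) and the data.
#' @export
fit_calibration <- function(x_manual, y_detected,
                            variable_name = "variable", intercept = FALSE) {
  if (length(x_manual) != length(y_detected)) stop("x and y lengths differ")
  if (length(x_manual) < 2) stop("need at least 2 paired observations")
  if (all(x_manual == 0)) stop("degenerate regressor: all x are zero")
  fit <- if (intercept) lm(y_detected ~ x_manual) else lm(y_detected ~ 0 + x_manual)
  cf <- stats::coef(fit)
  slope <- unname(cf[["x_manual"]])
  structure(list(
    slope = slope,
    intercept = if (intercept) unname(cf[["(Intercept)"]]) else 0,
    r = cor(x_manual, y_detected),
    variable_name = variable_name,
    data = tibble::tibble(x_manual = x_manual, y_detected = y_detected)
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: y = %.4g x%s (r = %.3f)\n",
              x$variable_name, x$slope,
              if (x$intercept != 0) sprintf(" + %.4g", x$intercept) else "",
              x$r))
  invisible(x)
}

#' Bundled default calibration for the reference device
#'
#' Published manual-vs-automated through-origin calibration slopes for the
#' reference wide-field capillaroscope workflow: number 2.014 (r = 0.96),
#' total area 1.311 (r = 0.99), average area 0.604 (r = 0.99). Use these to
#' convert detections on comparable data to manual-annotation scale when no
#' local calibration is available.
#'
#' @return named list of `calibration_model`s: `number`, `total_area`,
#'   `average_area`.
#' @export
default_calibration <- function() {
  mk <- function(slope, r, name)
    structure(list(slope = slope, intercept = 0, r = r, variable_name = name,
                   data = NULL), class = "calibration_model")
  list(number = mk(2.014, 0.96, "number"),
       total_area = mk(1.311, 0.99, "total_area"),
       average_area = mk(0.604, 0.99, "average_area"))
}

#' Invert a calibration: detected value to manual-annotation scale
#'
#' Solves `y = slope * x` for `x`: `x_hat = y / slope` (the intercept, if
#' one was fitted, is subtracted first).
#'
#' @param y_detected detected value(s).
#' @param model a `calibration_model`.
#' @return calibrated value(s) on the manual scale.
#' @export
apply_calibration <- function(y_detected, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.finite(model$slope) || model$slope <= 0)
    stop("calibration slope must be positive")
  (y_detected - model$intercept) / model$slope
}

#' Calibration scatter plot
#'
#' @param object a `calibration_model` fitted with data.
#' @param ... unused.
#' @return a ggplot: pairs, the through-origin fit, and the identity line.
#' @export
autoplot.calibration_model <- function(object, ...) {
  if (is.null(object$data)) stop("no data stored in this calibration model")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$x_manual, y = .data$y_detected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "manual annotation", y = "automated detection",
                  title = sprintf("%s: y = %.3f x (r = %.2f)",
                                  object$variable_name, object$slope, object$r))
}
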