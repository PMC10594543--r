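# Shared low-level helpers. Images are kept as integer arrays in [0, 255]:
# H x W x 3 (R, G, B) for color stills, H x W matrices with values {0, 255}
# for binary masks. Spatial coordinates reported to users (offsets, bounding
# boxes, centroids) are 0-based x/y to match the imaging-tool convention.

round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

as_uint8 <- function(x) {
  x <- clip8(round_half_up(x))
  storage.mode(x) <- "integer"
  x
}

is_rgb8 <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L &&
    is.numeric(img) && min(img) >= 0 && max(img) <= 255
}

assert_rgb8 <- function(img, what = "image") {
  if (!is_rgb8(img)) stop(what, " must be an 8-bit RGB array (H x W x 3, values in [0, 255])")
  invisible(img)
}

assert_binary_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop(what, " must be a matrix")
  bad <- setdiff(unique(as.vector(mask)), c(0, 255))
  if (length(bad))
    stop(what, " must be binary {0, 255}; found values: ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(mask)
}

#' Multiplicative vignetting field
#'
#' Radial illumination falloff as seen in wide-field contact capillaroscopy:
#' `1 - strength * (d / d_max)^2`, where `d` is the distance from the canvas
#' center and `d_max` the center-to-corner distance. Multiplying an evenly
#' lit scene by this field emulates the darkened periphery that flat-fielding
#' is meant to remove.
#'
#' @param height_px,width_px canvas size in pixels.
#' @param strength vignetting strength in `[0, 1)`; 0 means no falloff.
#' @return an `height_px` x `width_px` matrix of factors in `(0, 1]`.
#' @export
vignette_field <- function(height_px, width_px, strength) {
  stopifnot(strength >= 0, strength < 1)
  cy <- (height_px + 1) / 2
  cx <- (width_px + 1) / 2
  d2 <- outer((seq_len(height_px) - cy)^2, (seq_len(width_px) - cx)^2, `+`)
  1 - strength * d2 / max(d2)
}

#' Central crop of an image or mask
#'
#' Removes a `margin_px` border on every side. Used to place simulator ground
#' truth on the same grid as a stabilized still: the stabilization template is
#' the central crop of the first frame, so when the first frame is unshifted
#' the matching ground-truth view is the central crop of the scene mask.
#'
#' @param x matrix (mask) or H x W x 3 array.
#' @param margin_px border width in pixels.
#' @return the cropped matrix or array.
#' @export
crop_margin <- function(x, margin_px) {
  d <- dim(x)
  if (2 * margin_px >= min(d[1:2])) stop("margin too large for image")
  rows <- (margin_px + 1):(d[1] - margin_px)
  cols <- (margin_px + 1):(d[2] - margin_px)
  if (length(d) == 3L) x[rows, cols, , drop = FALSE] else x[rows, cols, drop = FALSE]
}
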