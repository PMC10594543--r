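# Video -> annotated-ready still: stabilization by exhaustive zero-mean
# normalized cross-correlation template matching, per-pixel minimum-green
# temporal compositing, flat-field division by a box-mean image, and
# per-channel histogram equalization + gamma correction.

#' Frame stack container
#'
#' An ordered sequence of same-shape 8-bit RGB frames with physical metadata.
#'
#' @param frames list of H x W x 3 arrays, values in `[0, 255]`, channel
#'   order (R, G, B).
#' @param um_per_px pixel pitch in micrometres.
#' @param fps frame rate, frames/s.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, um_per_px = NA_real_, fps = NA_real_) {
  if (!is.list(frames) || length(frames) < 1) stop("need at least one frame")
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    assert_rgb8(frames[[i]], sprintf("frame %d", i))
    if (!identical(dim(frames[[i]]), d1))
      stop(sprintf("frame %d has shape %s, expected %s", i,
                   paste(dim(frames[[i]]), collapse = "x"),
                   paste(d1, collapse = "x")))
  }
  structure(list(frames = frames, um_per_px = um_per_px, fps = fps),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %s um/px, %s fps\n",
              length(x$frames), d[2], d[1],
              format(x$um_per_px), format(x$fps)))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Stabilize a frame stack by template matching
#'
#' The central `(W - 2m) x (H - 2m)` crop of the first frame is the template
#' (for the reference device, a margin of 50 px on a 4000 x 3000 frame gives
#' the 3900 x 2900 template). For every frame, the position maximizing the
#' zero-mean normalized cross-correlation of the green channel with the
#' template is found by exhaustive search over all valid integer positions;
#' the crop at that position becomes the aligned frame. Correctable drift is
#' within +/- `template_margin_px` in each axis. Ties in the similarity map
#' are broken by the smallest (y, x) position.
#'
#' @param stack a [frame_stack()].
#' @param template_margin_px margin `m` in pixels (default 50).
#' @return a `stabilization_result`: `aligned` (a [frame_stack()] of
#'   template-sized frames), `offsets` (tibble: frame, x, y, score; x/y are
#'   0-based match positions — a static stack yields (m, m)), and
#'   `template_size` (w, h).
#' @export
stabilize <- function(stack, template_margin_px = 50) {
  stopifnot(inherits(stack, "frame_stack"))
  m <- as.integer(template_margin_px)
  d <- dim(stack$frames[[1]])
  if (d[1] <= 2 * m || d[2] <= 2 * m)
    stop("frame dimensions must exceed twice the template margin")
  th <- d[1] - 2L * m; tw <- d[2] - 2L * m
  templ <- stack$frames[[1]][(m + 1):(m + th), (m + 1):(m + tw), 2]
  if (sd(as.vector(templ)) == 0) stop("untextured template")
  n <- length(stack$frames)
  xs <- integer(n); ys <- integer(n); sc <- numeric(n)
  aligned <- vector("list", n)
  for (k in seq_len(n)) {
    g <- stack$frames[[k]][, , 2]
    best <- cpp_zncc_best_match(g * 1.0, templ * 1.0)
    xs[k] <- best$x; ys[k] <- best$y; sc[k] <- best$score
    aligned[[k]] <- stack$frames[[k]][(best$y + 1):(best$y + th),
                                      (best$x + 1):(best$x + tw), , drop = FALSE]
  }
  structure(list(
    aligned = frame_stack(aligned, um_per_px = stack$um_per_px, fps = stack$fps),
    offsets = tibble::tibble(frame = seq_len(n), x = xs, y = ys, score = sc),
    template_size = c(w = tw, h = th),
    margin_px = m
  ), class = "stabilization_result")
}

#' Minimum-green temporal composite
#'
#' Capillaries are visible only in the frames where red blood cells transit,
#' and RBCs depress the green channel. The composite therefore selects, per
#' pixel, the frame with the lowest green value across the stack and carries
#' that frame's full (R, G, B) triplet, producing a still in which every
#' vessel segment that ever carried an RBC appears filled. Ties are broken by
#' the earliest frame index.
#'
#' @param stack an aligned [frame_stack()].
#' @return a `composite_image`: `image` (8-bit RGB array) and
#'   `source_frame_index` (H x W matrix of 1-based frame indices).
#' @export
min_green_composite <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  frames <- stack$frames
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  chan <- function(fr, c) matrix(fr[, , c], h, w)
  gmin <- chan(frames[[1]], 2)
  idx <- matrix(1L, h, w)
  for (k in seq_along(frames)[-1]) {
    g <- chan(frames[[k]], 2)
    upd <- g < gmin       # strict: earliest frame wins ties
    gmin[upd] <- g[upd]
    idx[upd] <- k
  }
  out <- frames[[1]]
  for (k in unique(as.vector(idx))) {
    if (k == 1L) next
    sel <- idx == k
    for (c in 1:3) {
      ch <- chan(out, c); src <- chan(frames[[k]], c)
      ch[sel] <- src[sel]
      out[, , c] <- ch
    }
  }
  structure(list(image = out, source_frame_index = idx),
            class = "composite_image")
}

#' Flat-field configuration
#'
#' @param kernel_radius_px box mean-filter radius in pixels (default 300, the
#'   reference full-scale setting; reduce proportionally for small images).
#' @param border_mode padding for the mean filter: "reflect" or "replicate".
#' @param rescale how the division ratio returns to 8 bits:
#'   "global_channel_mean" multiplies by the channel's global mean,
#'   "fixed_midgray" multiplies by 128.
#' @return a `flat_field_config` list.
#' @export
flat_field_config <- function(kernel_radius_px = 300,
                              border_mode = c("reflect", "replicate"),
                              rescale = c("global_channel_mean", "fixed_midgray")) {
  if (kernel_radius_px < 1) stop("kernel_radius_px must be >= 1")
  list(kernel_radius_px = as.integer(kernel_radius_px),
       border_mode = match.arg(border_mode),
       rescale = match.arg(rescale))
}

pad_index <- function(n, r, mode) {
  if (r == 0) return(seq_len(n))
  idx <- if (mode == "reflect") {
    c(seq(r + 1, 2), seq_len(n), seq(n - 1, n - r))  # mirror, edge not repeated
  } else {
    c(rep(1L, r), seq_len(n), rep(n, r))
  }
  pmin(pmax(idx, 1L), n)
}

pad_matrix <- function(m, r, mode) {
  m[pad_index(nrow(m), r, mode), pad_index(ncol(m), r, mode), drop = FALSE]
}

# exact (2r+1)^2 box mean via summed-area table on a padded matrix
box_mean <- function(m, r, mode = "reflect") {
  p <- pad_matrix(m, r, mode)
  S <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed cumulative sum
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  h <- nrow(m); w <- ncol(m); k <- 2 * r + 1
  i2 <- (1:h) + 2 * r; j2 <- (1:w) + 2 * r
  (S[i2 + 1, j2 + 1, drop = FALSE] - S[i2 + 1 - k, j2 + 1, drop = FALSE] -
     S[i2 + 1, j2 + 1 - k, drop = FALSE] + S[i2 + 1 - k, j2 + 1 - k, drop = FALSE]) / k^2
}

#' Remove smooth brightness unevenness (flat-fielding)
#'
#' Each channel is divided by a heavily box-mean-filtered copy of itself
#' (radius `cfg$kernel_radius_px`), removing vignetting and other smooth
#' illumination structure while preserving fine detail. The denominator is
#' floored at 1 to guard dark corners, and the ratio is rescaled to 8 bits
#' (default: multiplied by the channel's global mean, rounded half up,
#' clipped to `[0, 255]`). A constant image is a fixed point.
#'
#' @param image a `composite_image` or an 8-bit RGB array.
#' @param cfg a [flat_field_config()].
#' @return an 8-bit RGB array.
#' @export
flatten_illumination <- function(image, cfg = flat_field_config()) {
  if (inherits(image, "composite_image")) image <- image$image
  assert_rgb8(image)
  out <- array(0L, dim(image))
  for (c in 1:3) {
    ch <- image[, , c] * 1.0
    denom <- pmax(box_mean(ch, cfg$kernel_radius_px, cfg$border_mode), 1)
    ratio <- ch / denom
    scale <- if (cfg$rescale == "global_channel_mean") mean(ch) else 128
    out[, , c] <- as_uint8(ratio * scale)
  }
  out
}

#' Contrast-enhancement configuration
#'
#' @param gamma gamma-correction exponent (default 0.3, which strongly
#'   brightens the dark vessel signal).
#' @param apply_equalization run per-channel histogram equalization before the
#'   gamma map (default `TRUE`).
#' @return a `contrast_config` list.
#' @export
contrast_config <- function(gamma = 0.3, apply_equalization = TRUE) {
  if (gamma <= 0) stop("gamma must be > 0")
  list(gamma = gamma, apply_equalization = isTRUE(apply_equalization))
}

equalize_channel <- function(ch) {
  v <- as.vector(ch)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  nz <- which(counts > 0)
  cdf_min <- cdf[nz[1]]
  n <- length(v)
  if (n == cdf_min) return(ch)  # constant channel: degenerate histogram
  lut <- as.integer(round_half_up(pmax(cdf - cdf_min, 0) / (n - cdf_min) * 255))
  matrix(lut[v + 1L], nrow(ch), ncol(ch))
}

#' Enhance contrast (equalization then gamma)
#'
#' Per channel: standard 256-bin histogram equalization (cumulative histogram
#' normalized from its first occupied bin, the common 8-bit convention),
#' followed by the gamma map `round(255 * (v / 255) ^ gamma)`. The order is
#' fixed: equalization first. Endpoints are preserved by the gamma map
#' (0 -> 0, 255 -> 255 for any gamma > 0).
#'
#' @param image an 8-bit RGB array.
#' @param cfg a [contrast_config()].
#' @return an 8-bit RGB array.
#' @export
enhance_contrast <- function(image, cfg = contrast_config()) {
  assert_rgb8(image)
  storage.mode(image) <- "integer"
  out <- array(0L, dim(image))
  glut <- as.integer(round_half_up(255 * (0:255 / 255) ^ cfg$gamma))
  for (c in 1:3) {
    ch <- image[, , c]
    if (cfg$apply_equalization) ch <- equalize_channel(ch)
    out[, , c] <- matrix(glut[ch + 1L], dim(image)[1], dim(image)[2])
  }
  out
}

#' Full video preprocessing: stabilize, composite, flatten, enhance
#'
#' Runs the four preprocessing stages in their canonical order and returns
#' the contrast-enhanced still together with the intermediate results needed
#' for provenance (stabilization offsets, composite source-frame map).
#'
#' @param stack a raw [frame_stack()].
#' @param template_margin_px stabilization margin (default 50; the output
#'   still is smaller than the input frames by twice this margin).
#' @param flat a [flat_field_config()].
#' @param con a [contrast_config()].
#' @return a `preprocessed_still` list: `still` (8-bit RGB),
#'   `stabilization` (offsets tibble + template size), and
#'   `source_frame_index`.
#' @export
preprocess_video <- function(stack, template_margin_px = 50,
                             flat = flat_field_config(),
                             con = contrast_config()) {
  st <- stabilize(stack, template_margin_px)
  comp <- min_green_composite(st$aligned)
  flat_img <- flatten_illumination(comp, flat)
  still <- enhance_contrast(flat_img, con)
  structure(list(
    still = still,
    stabilization = st[c("offsets", "template_size", "margin_px")],
    source_frame_index = comp$source_frame_index
  ), class = "preprocessed_still")
}
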