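# Readers/writers for the on-disk formats: PNG/TIFF frame directories,
# multi-page TIFF stacks, single-channel {0, 255} mask PNGs, RGB stills.
# All images are normalized to (R, G, B) channel order and 0-255 integers on
# read. Lossy video containers are intentionally not read (inter-frame
# compression corrupts the minimum-green statistic); extract frames first.

VIDEO_EXTENSIONS <- c("mp4", "avi", "mov", "mkv", "webm", "m4v", "wmv")

# float image from png/tiff readers -> 8-bit RGB integer array
to_rgb8 <- function(img, what = "image") {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  d <- dim(img)
  if (length(d) != 3L) stop(what, ": unsupported image layout")
  if (d[3] == 2L) img <- array(rep(img[, , 1], 3), dim = c(d[1:2], 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop(what, ": expected 1, 3 or 4 channels")
  if (max(img) <= 1) img <- img * 255
  as_uint8(img)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext %in% VIDEO_EXTENSIONS) {
    stop("video containers are not read directly (lossy inter-frame ",
         "compression corrupts the min-G composite); extract frames to a ",
         "PNG/TIFF directory first: ", path)
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Read a frame stack from disk
#'
#' Accepts a directory of same-shape PNG/TIFF frames (sorted by filename; the
#' writer uses `frame_0000.png`, `frame_0001.png`, ...) or a single
#' multi-page TIFF. Channel order is normalized to (R, G, B); grayscale
#' frames are expanded to three channels.
#'
#' @param path frame directory or multi-page TIFF file.
#' @param um_per_px,fps physical metadata to attach.
#' @return a [frame_stack()].
#' @export
read_frames <- function(path, um_per_px = NA_real_, fps = NA_real_) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    frames <- lapply(files, function(f) to_rgb8(read_image_file(f), basename(f)))
    d1 <- dim(frames[[1]])
    for (i in seq_along(frames))
      if (!identical(dim(frames[[i]]), d1))
        stop(sprintf("frame %s has shape %s, expected %s", basename(files[i]),
                     paste(dim(frames[[i]]), collapse = "x"),
                     paste(d1, collapse = "x")))
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% VIDEO_EXTENSIONS) read_image_file(path)  # raises the advice
    if (!ext %in% c("tif", "tiff"))
      stop("expected a frame directory or a multi-page TIFF: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_rgb8)
  }
  frame_stack(frames, um_per_px = um_per_px, fps = fps)
}

#' Write a frame stack as numbered PNG files
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix; files are `<prefix>0000.png`, ...
#' @return the file paths, invisibly.
#' @export
write_frames <- function(stack, dir, prefix = "frame_") {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(stack$frames), function(k) {
    p <- file.path(dir, sprintf("%s%04d.png", prefix, k - 1))
    png::writePNG(stack$frames[[k]] / 255, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read / write an RGB still image (PNG)
#'
#' @param path PNG file path.
#' @return `read_still` returns an 8-bit RGB array.
#' @export
read_still <- function(path) to_rgb8(read_image_file(path), basename(path))

#' @rdname read_still
#' @param image 8-bit RGB array.
#' @export
write_still <- function(image, path) {
  assert_rgb8(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read / write a binary capillary mask (PNG, capillary = 255)
#'
#' On read, a 3-channel PNG is accepted if its channels are identical and is
#' collapsed to a single channel; any value outside {0, 255} is an error
#' listing the offending values.
#'
#' @param path PNG file path.
#' @return `read_mask` returns an H x W integer matrix with values {0, 255}.
#' @export
read_mask <- function(path) {
  img <- read_image_file(path)
  if (!is.matrix(img)) {
    d <- dim(img)
    if (length(d) == 3L && d[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    if (length(d) == 3L && dim(img)[3] == 3L) {
      if (max(abs(img[, , 1] - img[, , 2])) > 0 ||
          max(abs(img[, , 1] - img[, , 3])) > 0)
        stop("multi-channel mask with inconsistent channels: ", path)
      img <- img[, , 1]
    } else if (length(d) == 3L && d[3] == 2L) {
      img <- img[, , 1]
    }
  }
  m <- round_half_up(img * 255)
  storage.mode(m) <- "integer"
  bad <- setdiff(unique(as.vector(m)), c(0L, 255L))
  if (length(bad))
    stop("mask is not binary {0, 255}; offending values: ",
         paste(utils::head(sort(bad), 10), collapse = ", "), " in ", path)
  m
}

#' @rdname read_mask
#' @param mask H x W matrix with values {0, 255}.
#' @export
write_mask <- function(mask, path) {
  assert_binary_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Write stabilization or jitter offsets as CSV
#'
#' @param offsets a tibble/data.frame with a `frame` column (plus x/y or
#'   dx/dy columns).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_offsets_csv <- function(offsets, path) {
  write.csv(offsets, path, row.names = FALSE)
  invisible(path)
}

#' Write a region table as CSV
#'
#' @param table a [label_regions()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
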