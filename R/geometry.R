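#' Reference device geometry
#'
#' Optical geometry of the wide-field portable video capillaroscope this
#' package targets: a 4000 x 3000 px sensor imaging a 7.4 mm x 5.5 mm skin
#' field at 30 frames/s, i.e. a pixel pitch of 1.85 um/px.
#'
#' @return a list with `fov_mm` (width, height), `sensor_px` (width, height),
#'   `fps`, and the derived `um_per_px`.
#' @examples
#' device_geometry()$um_per_px  # 1.85
#' @export
device_geometry <- function() {
  fov_mm <- c(width = 7.4, height = 5.5)
  sensor_px <- c(width = 4000L, height = 3000L)
  list(
    fov_mm = fov_mm,
    sensor_px = sensor_px,
    fps = 30,
    um_per_px = unname(fov_mm[["width"]] * 1000 / sensor_px[["width"]])
  )
}

#' Physical extent of a pixel span
#'
#' Converts a pixel count to millimetres at a given pixel pitch, rounded to
#' one decimal as customarily quoted for fields of view (e.g. 3900 px at
#' 1.85 um/px is 7.2 mm; 1300 px is 2.4 mm).
#'
#' @param n_px pixel count.
#' @param um_per_px pixel pitch in micrometres.
#' @param digits decimals to round the millimetre value to.
#' @return extent in mm.
#' @export
fov_extent_mm <- function(n_px, um_per_px = device_geometry()$um_per_px,
                          digits = 1) {
  round(n_px * um_per_px / 1000, digits)
}
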