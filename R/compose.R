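#' HYDROPS image composition: PPI minus PEI
#'
#' Element-wise subtraction of the positive endolymph image from the positive
#' perilymph image. On the result, perilymph is positive and endolymph
#' negative; negative values are preserved (no clipping), and the arithmetic
#' is carried out in floating point regardless of the input storage type.
#'
#' @param ppi,pei [eh_volume()] objects with tags `"PPI"` and `"PEI"` on the
#'   same grid.
#' @return An [eh_volume()] tagged `"HYDROPS"`.
#' @examples
#' vs <- c(0.5, 0.5, 1)
#' h <- compose_hydrops(eh_volume(array(100, c(2, 2, 1)), vs, "PPI"),
#'                      eh_volume(array(30, c(2, 2, 1)), vs, "PEI"))
#' h$data[1, 1, 1]  # 70
#' @export
compose_hydrops <- function(ppi, pei) {
  stopifnot(inherits(ppi, "eh_volume"), inherits(pei, "eh_volume"))
  if (ppi$tag != "PPI" || pei$tag != "PEI")
    stop("compose_hydrops expects tags PPI and PEI, got ",
         ppi$tag, " and ", pei$tag)
  check_same_grid(ppi, pei, "PPI", "PEI")
  eh_volume(ppi$data - pei$data, ppi$voxel_size_mm, "HYDROPS")
}

#' HYDROPS-Mi2 composition: HYDROPS times MRC
#'
#' Element-wise product of the HYDROPS subtraction image with the MR
#' cisternography image. Multiplying by the (non-negative in noiseless
#' conditions) fluid-bright MRC image suppresses non-fluid background while
#' preserving the sign of the HYDROPS value wherever MRC is positive -- the
#' sign carries the endolymph/perilymph classification.
#'
#' @param hydrops,mrc [eh_volume()] objects with tags `"HYDROPS"` and `"MRC"`
#'   on the same grid.
#' @return An [eh_volume()] tagged `"HYDROPS-Mi2"`.
#' @examples
#' vs <- c(0.5, 0.5, 1)
#' m <- compose_mi2(eh_volume(array(-50, c(1, 1, 1)), vs, "HYDROPS"),
#'                  eh_volume(array(2, c(1, 1, 1)), vs, "MRC"))
#' m$data[1, 1, 1]  # -100
#' @export
compose_mi2 <- function(hydrops, mrc) {
  stopifnot(inherits(hydrops, "eh_volume"), inherits(mrc, "eh_volume"))
  if (hydrops$tag != "HYDROPS" || mrc$tag != "MRC")
    stop("compose_mi2 expects tags HYDROPS and MRC, got ",
         hydrops$tag, " and ", mrc$tag)
  check_same_grid(hydrops, mrc, "HYDROPS", "MRC")
  eh_volume(hydrops$data * mrc$data, hydrops$voxel_size_mm, "HYDROPS-Mi2")
}

#' Display window/level settings
#'
#' The linear display transform used when exporting figures. The defaults
#' (level 400, width 1000) are the settings used for visual assessment of
#' HYDROPS-Mi2 images. Windowing is for display only: EH-ratio counting is
#' always performed on raw signed values, because the window transform
#' destroys the sign of a voxel.
#'
#' @param level Window center.
#' @param width Window width (> 0).
#' @return An object of class `window_level`.
#' @export
window_level <- function(level = 400, width = 1000) {
  if (!is.numeric(width) || width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width), class = "window_level")
}

#' Apply a display window to a volume
#'
#' Linear map of voxel values to display intensities in `[0, 1]`: values at
#' or below `level - width/2` map to 0, values at or above `level + width/2`
#' map to 1, and the level maps to mid-gray.
#'
#' @param volume An [eh_volume()] (or plain numeric array).
#' @param wl A [window_level()].
#' @return Numeric array of display values in `[0, 1]` with the input's
#'   dimensions.
#' @examples
#' apply_window(array(c(-100, 400, 900), c(3, 1, 1)))
#' @export
apply_window <- function(volume, wl = window_level()) {
  stopifnot(inherits(wl, "window_level"))
  x <- if (inherits(volume, "eh_volume")) volume$data else volume
  pmin(pmax((x - (wl$level - wl$width / 2)) / wl$width, 0), 1)
}
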