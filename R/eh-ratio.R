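#' One EH-ratio measurement
#'
#' Container for a single endolymphatic-hydrops ratio: the site and side it
#' was measured at, the exact numerator and denominator pixel counts, and
#' the method that produced it.
#'
#' @param site Measurement site (e.g. `"cochlea"`, `"vestibule"`,
#'   `"saccule"`, `"utricle"`, `"canal_anterior_ampullary"`).
#' @param side `"affected"`, `"unaffected"`, or `"control"`.
#' @param numerator_pixels,denominator_pixels Nonnegative integer counts;
#'   the denominator must be positive.
#' @param method `"mri_negative_pixel"` or `"histo_area"`.
#' @param ear_id Optional ear identifier.
#' @return An object of class `eh_measurement` with `ratio` equal to
#'   `numerator_pixels / denominator_pixels` exactly.
#' @export
eh_measurement <- function(site, side, numerator_pixels, denominator_pixels,
                           method = c("mri_negative_pixel", "histo_area"),
                           ear_id = NA_character_) {
  method <- match.arg(method)
  if (denominator_pixels <= 0)
    stop("denominator must be positive")
  if (numerator_pixels < 0 || numerator_pixels > denominator_pixels)
    stop("numerator must lie in [0, denominator]")
  structure(list(ear_id = ear_id, site = site, side = side,
                 numerator_pixels = as.integer(numerator_pixels),
                 denominator_pixels = as.integer(denominator_pixels),
                 ratio = numerator_pixels / denominator_pixels,
                 method = method),
            class = "eh_measurement")
}

#' @export
print.eh_measurement <- function(x, ...) {
  cat(sprintf("EH ratio [%s, %s, %s]: %d / %d = %.3f\n",
              x$site, x$side, x$method,
              x$numerator_pixels, x$denominator_pixels, round(x$ratio, 3)))
  invisible(x)
}

#' Collect EH measurements into a data frame
#'
#' @param ... `eh_measurement` objects or lists of them.
#' @return A data.frame with one row per measurement.
#' @export
measurements_table <- function(...) {
  xs <- list(...)
  xs <- unlist(lapply(xs, function(x)
    if (inherits(x, "eh_measurement")) list(x) else x), recursive = FALSE)
  do.call(rbind, lapply(xs, function(m)
    data.frame(ear_id = m$ear_id, site = m$site, side = m$side,
               method = m$method, numerator = m$numerator_pixels,
               denominator = m$denominator_pixels, ratio = m$ratio,
               stringsAsFactors = FALSE)))
}

roi_values <- function(mi2, roi) {
  stopifnot(inherits(mi2, "eh_volume"), inherits(roi, "roi_mask"))
  d <- dim(mi2$data)
  if (roi$slice < 1L || roi$slice > d[3])
    stop("ROI slice ", roi$slice, " outside volume (", d[3], " slices)")
  if (!identical(dim(roi$mask), d[1:2]))
    stop("ROI mask extends outside volume: mask is ",
         paste(dim(roi$mask), collapse = "x"), ", slice is ",
         paste(d[1:2], collapse = "x"))
  mi2$data[, , roi$slice][roi$mask]
}

#' EH ratio by negative-pixel counting on a HYDROPS-Mi2 volume
#'
#' The MRI EH ratio: the number of ROI pixels with strictly negative
#' HYDROPS-Mi2 signal (endolymph) divided by the total number of pixels in
#' the ROI. Counting is performed on raw signed values, never on windowed
#' display values; pixels at exactly zero (background, or zero
#' cisternography signal) count as non-endolymph.
#'
#' @param mi2 An [eh_volume()] tagged `"HYDROPS-Mi2"`.
#' @param roi An [roi_mask()].
#' @param side Side class recorded in the measurement.
#' @param ear_id Optional ear identifier.
#' @return An [eh_measurement()] with method `"mri_negative_pixel"`.
#' @examples
#' vs <- c(0.5, 0.5, 1)
#' v <- eh_volume(array(c(-1, -2, -3, rep(1, 7)), c(10, 1, 1)), vs, "HYDROPS-Mi2")
#' roi <- roi_mask(matrix(TRUE, 10, 1), 1, "cochlea")
#' eh_ratio_mri(v, roi)$ratio  # 0.3
#' @export
eh_ratio_mri <- function(mi2, roi, side = "affected", ear_id = NA_character_) {
  if (mi2$tag != "HYDROPS-Mi2")
    warning("eh_ratio_mri is defined on HYDROPS-Mi2 volumes; got tag ", mi2$tag)
  vals <- roi_values(mi2, roi)
  eh_measurement(site = roi$site, side = side,
                 numerator_pixels = sum(vals < 0),
                 denominator_pixels = length(vals),
                 method = "mri_negative_pixel", ear_id = ear_id)
}

#' Signal histogram of an ROI with negative-pixel count
#'
#' The histogram-tool view of an ROI: binned counts of the HYDROPS-Mi2
#' values inside the ROI, with the count of strictly negative pixels. A bin
#' edge is always placed at zero so the negative tail is exactly separable;
#' `n_negative` is guaranteed to equal the numerator of [eh_ratio_mri()] on
#' the same inputs.
#'
#' @param mi2 An [eh_volume()].
#' @param roi An [roi_mask()].
#' @param n_bins Approximate number of bins.
#' @return A list with `breaks`, `counts`, `n_negative`, `n_total`.
#' @export
negative_pixel_histogram <- function(mi2, roi, n_bins = 64) {
  vals <- roi_values(mi2, roi)
  rng <- range(vals)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- pretty(rng, n = n_bins)
  # force an edge at zero so negative and non-negative bins never mix
  if (!any(breaks == 0) && rng[1] < 0 && rng[2] > 0)
    breaks <- sort(c(breaks, 0))
  breaks <- unique(sort(c(breaks, rng)))
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       n_negative = sum(vals < 0), n_total = length(vals))
}
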