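#' Region-of-interest mask on one slice
#'
#' A 2D boolean mask bound to a slice index and a site, with a provenance
#' note recording the rule (or file) that produced it.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param slice Integer slice index the mask applies to.
#' @param site `"cochlea"` or `"vestibule"`.
#' @param provenance Free-text note on how the mask was obtained.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, slice, site = c("cochlea", "vestibule"),
                     provenance = "manual") {
  site <- match.arg(site)
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix")
  if (!any(mask))
    stop("empty ROI: mask has no true pixel")
  structure(list(mask = mask, slice = as.integer(slice), site = site,
                 provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask site=%s slice=%d, %d pixels (%s)\n",
              x$site, x$slice, sum(x$mask), x$provenance))
  invisible(x)
}

#' Angular arc coverage of a 2D mask around a center
#'
#' Measures over how many degrees of a full turn a (ring-like) mask is
#' visible: the angle of every true pixel relative to `center` is binned
#' into `bin_deg`-wide bins over `[0, 360)` and coverage is the number of
#' occupied bins times the bin width. This operationalizes the
#' "ring visible for more than 240 degrees" slice-selection criterion.
#'
#' @param mask Logical matrix (a slice of a label volume, say). An empty
#'   mask yields coverage 0.
#' @param center Numeric length-2 center (pixel coordinates). Defaults to
#'   the mask centroid.
#' @param bin_deg Angular bin width in degrees.
#' @return An object of class `arc_coverage` with fields `degrees`, `center`,
#'   `bin_deg`.
#' @examples
#' m <- outer(1:64, 1:64, function(x, y) {
#'   r <- sqrt((x - 32)^2 + (y - 32)^2); r > 20 & r < 24
#' })
#' arc_coverage(m)$degrees  # 360
#' @export
arc_coverage <- function(mask, center = NULL, bin_deg = 1) {
  stopifnot(is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(structure(list(degrees = 0, center = c(NA_real_, NA_real_),
                          bin_deg = bin_deg), class = "arc_coverage"))
  }
  if (is.null(center))
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
  ang <- atan2(idx[, 2] - center[2], idx[, 1] - center[1]) * 180 / pi
  ang <- ang %% 360
  bins <- unique(floor(ang / bin_deg))
  structure(list(degrees = length(bins) * bin_deg, center = center,
                 bin_deg = bin_deg),
            class = "arc_coverage")
}

#' @export
print.arc_coverage <- function(x, ...) {
  cat(sprintf("arc_coverage %.1f deg (bin %g deg, center %.1f, %.1f)\n",
              x$degrees, x$bin_deg, x$center[1], x$center[2]))
  invisible(x)
}

#' Select the representative cochlear slice
#'
#' Scans the label volume for slices on which all three cochlear turns
#' (basal, middle, apical) are visible. If exactly one slice qualifies it is
#' returned directly; if several qualify, the slice with the greatest
#' modiolus in-plane extent (pixel count; ties broken toward the lower,
#' i.e. more inferior, index) is chosen.
#'
#' @param labels An [eh_label_volume()].
#' @return Integer slice index.
#' @export
select_cochlea_slice <- function(labels) {
  stopifnot(inherits(labels, "eh_label_volume"))
  lb <- eh_labels()
  nz <- dim(labels$labels)[3]
  has_all <- logical(nz)
  mod_count <- integer(nz)
  for (z in seq_len(nz)) {
    pl <- labels$labels[, , z]
    has_all[z] <- all(vapply(c("basal", "middle", "apical"), function(tn)
      any(pl %in% turn_codes(tn)), logical(1)))
    mod_count[z] <- sum(pl == lb[["modiolus"]])
  }
  cand <- which(has_all)
  if (length(cand) == 0L)
    stop("no representative cochlear slice: no slice shows all three turns")
  if (length(cand) == 1L)
    return(cand)
  cand[which.max(mod_count[cand])]
}

#' Select the representative vestibular slice and ROI
#'
#' Returns the lowest (most inferior) slice on which the lateral
#' semicircular canal ring is visible for strictly more than 240 degrees of
#' arc, together with the vestibular ROI on that slice: the vestibule label
#' minus any ampulla-labeled pixels. Arc coverage is computed with
#' [arc_coverage()] in 1-degree bins around the centroid of the full 3D ring
#' projected to the plane.
#'
#' @param labels An [eh_label_volume()]. Slice index 1 is taken to be the
#'   most inferior slice (set `ascending_superior = FALSE` if the volume is
#'   stored the other way around).
#' @param min_arc_deg Visibility criterion in degrees (strict `>`).
#' @param ascending_superior Whether slice indices ascend from inferior to
#'   superior.
#' @param bin_deg Angular bin width for the coverage measurement. The
#'   default (`NULL`) adapts to the ring resolution: one pixel at radius `r`
#'   subtends about `57.3 / r` degrees, so bins are widened to roughly twice
#'   that at the ring's median radius (at least 1 degree) -- a thin
#'   low-resolution ring would otherwise leave most 1-degree bins empty and
#'   understate its visibility. The criterion itself only needs coarse
#'   angular resolution.
#' @return A list with `slice` (integer) and `roi` ([roi_mask()]).
#' @export
select_vestibule_slice <- function(labels, min_arc_deg = 240,
                                   ascending_superior = TRUE, bin_deg = NULL) {
  stopifnot(inherits(labels, "eh_label_volume"))
  ring_codes <- lscc_ring_codes()
  nz <- dim(labels$labels)[3]
  ring3d <- array(labels$labels %in% ring_codes, dim(labels$labels))
  if (!any(ring3d))
    stop("no qualifying vestibular slice: no lateral canal ring labels present")
  # centroid of the full 3D ring projected in-plane: stable against partial arcs
  idx <- which(apply(ring3d, c(1, 2), any), arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  if (is.null(bin_deg)) {
    r_med <- stats::median(sqrt((idx[, 1] - center[1])^2 +
                                (idx[, 2] - center[2])^2))
    bin_deg <- max(1, ceiling(2 * (180 / pi) / r_med))
  }

  order_z <- if (ascending_superior) seq_len(nz) else rev(seq_len(nz))
  for (z in order_z) {
    cov <- arc_coverage(ring3d[, , z], center = center, bin_deg = bin_deg)
    if (cov$degrees > min_arc_deg) {
      pl <- labels$labels[, , z]
      m <- matrix(pl %in% vestibule_codes() & !(pl %in% ampulla_codes()),
                  nrow(pl), ncol(pl))
      if (!any(m))
        stop("no qualifying vestibular slice: vestibule label empty on slice ", z)
      return(list(slice = z,
                  roi = roi_mask(m, z, "vestibule",
                                 provenance = sprintf(
                                   "lowest slice with LSCC arc > %g deg (%.0f deg), ampulla excluded",
                                   min_arc_deg, cov$degrees))))
    }
  }
  stop("no qualifying vestibular slice: no slice has LSCC arc coverage > ",
       min_arc_deg, " degrees")
}

#' Cochlear ROI on a selected slice
#'
#' The cochlear ROI used for negative-pixel counting: all cochlear fluid
#' labels (the three turns' scalae) on the given slice. The contour is drawn
#' around the fluid-bright signal on cisternography, so the bony modiolus
#' core is not part of the ROI.
#'
#' @param labels An [eh_label_volume()].
#' @param slice Slice index, typically from [select_cochlea_slice()].
#' @return An [roi_mask()].
#' @export
cochlea_roi <- function(labels, slice) {
  stopifnot(inherits(labels, "eh_label_volume"))
  pl <- labels$labels[, , slice]
  m <- matrix(pl %in% cochlea_codes(), nrow(pl), ncol(pl))
  if (!any(m))
    stop("empty ROI: no cochlear labels on slice ", slice)
  roi_mask(m, slice, "cochlea",
           provenance = "cochlear fluid labels on representative slice")
}
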