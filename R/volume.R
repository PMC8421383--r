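#' MR volume container
#'
#' A light container for one 3D scalar MR volume: the voxel data, the voxel
#' size in mm, and a contrast tag identifying what the volume holds.
#'
#' @param data 3D numeric array of voxel values (finite).
#' @param voxel_size_mm Numeric vector of 3 positive voxel edge lengths (mm).
#' @param tag One of `"MRC"`, `"PPI"`, `"PEI"`, `"HYDROPS"`, `"HYDROPS-Mi2"`,
#'   `"other"`.
#' @return An object of class `eh_volume`.
#' @examples
#' v <- eh_volume(array(0, c(4, 4, 2)), c(0.5, 0.5, 1), "MRC")
#' dim(v$data)
#' @export
eh_volume <- function(data, voxel_size_mm = c(0.5, 0.5, 1.0),
                      tag = c("other", "MRC", "PPI", "PEI", "HYDROPS", "HYDROPS-Mi2")) {
  tag <- match.arg(tag)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume data must contain finite values only")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  structure(list(data = data * 1.0,  # force floating point: integer image
                                     # subtraction must never wrap
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tag = tag),
            class = "eh_volume")
}

#' @export
print.eh_volume <- function(x, ...) {
  cat(sprintf("eh_volume [%s] %s voxels, %s mm, range [%.3g, %.3g]\n",
              x$tag, paste(dim(x$data), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

grid_signature <- function(v) {
  paste0(paste(dim(v$data), collapse = "x"), " @ ",
         paste(format(v$voxel_size_mm), collapse = "x"), " mm")
}

check_same_grid <- function(a, b, what_a, what_b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)))
    stop("grid mismatch between ", what_a, " [", grid_signature(a), "] and ",
         what_b, " [", grid_signature(b), "]")
  invisible(TRUE)
}

#' Label volume container
#'
#' Integer anatomy labels on the same grid as the MR volumes (one most
#' specific compartment code per voxel, see [eh_labels()]), plus a logical
#' canal-territory mask marking the lateral-canal lumen outside the vestibule
#' boundary (kept separate because it overlays, rather than replaces,
#' compartment labels).
#'
#' @param labels 3D integer array of label codes.
#' @param territory Logical array of the same shape (canal territory), or
#'   `NULL` for all-false.
#' @param voxel_size_mm Numeric vector of 3 positive voxel sizes (mm).
#' @return An object of class `eh_label_volume`.
#' @export
eh_label_volume <- function(labels, territory = NULL,
                            voxel_size_mm = c(0.5, 0.5, 1.0)) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (is.null(territory))
    territory <- array(FALSE, dim(labels))
  if (!identical(dim(territory), dim(labels)))
    stop("territory mask must match the label grid")
  structure(list(labels = labels, territory = territory,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "eh_label_volume")
}

#' @export
print.eh_label_volume <- function(x, ...) {
  cat(sprintf("eh_label_volume %s voxels, %d distinct labels, %d territory voxels\n",
              paste(dim(x$labels), collapse = "x"),
              length(unique(as.vector(x$labels))), sum(x$territory)))
  invisible(x)
}
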