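#' Read and write volumes as NIfTI-1
#'
#' Volumes are exchanged as NIfTI-1 files (`.nii` / `.nii.gz`) with the
#' voxel size in the header. The contrast tag is not part of NIfTI and must
#' be restated when reading.
#'
#' @param volume An [eh_volume()] or [eh_label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns an [eh_volume()].
#' @export
write_volume_nifti <- function(volume, path) {
  if (inherits(volume, "eh_label_volume")) {
    img <- RNifti::asNifti(volume$labels * 1.0)
    dt <- "int16"
  } else {
    stopifnot(inherits(volume, "eh_volume"))
    img <- RNifti::asNifti(volume$data)
    dt <- "auto"
  }
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param tag Contrast tag to attach to the volume read from `path`.
#' @export
read_volume_nifti <- function(path, tag = "other") {
  img <- RNifti::readNifti(path)
  eh_volume(array(as.numeric(img), dim(img)),
            voxel_size_mm = RNifti::pixdim(img)[1:3], tag = tag)
}

#' Write and read a section image as grayscale PNG with a JSON sidecar
#'
#' The label matrix is stored losslessly as a grayscale PNG (label codes are
#' all below 256); a JSON sidecar (same path with `.json` appended) records
#' the pixel size, site metadata, and the mapping from label integers to
#' names.
#'
#' @param section An [eh_section()].
#' @param path Output path ending in `.png`.
#' @return `write_section_png` returns `path` invisibly; `read_section_png`
#'   returns an `eh_section` (without outlines or territory, which are
#'   generator-side ground truth).
#' @export
write_section_png <- function(section, path) {
  stopifnot(inherits(section, "eh_section"))
  png::writePNG(t(section$labels) / 255, path)
  meta <- list(pixel_size_mm = section$pixel_size_mm, site = section$site,
               canal = section$canal, region = section$region,
               ear_id = section$ear_id, side = section$side,
               herniation = section$herniation,
               labels = as.list(eh_labels()))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_section_png
#' @export
read_section_png <- function(path) {
  img <- png::readPNG(path)
  labels <- t(round(img * 255))
  storage.mode(labels) <- "integer"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(labels = labels,
                 territory = matrix(FALSE, nrow(labels), ncol(labels)),
                 pixel_size_mm = meta$pixel_size_mm, site = meta$site,
                 canal = meta$canal %||% NA_character_,
                 region = meta$region %||% NA_character_,
                 ear_id = meta$ear_id, side = meta$side,
                 herniation = meta$herniation, outlines = list()),
            class = "eh_section")
}

#' Write a cohort ground-truth table as CSV
#'
#' @param sim Result of [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(sim, path) {
  utils::write.csv(sim$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
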