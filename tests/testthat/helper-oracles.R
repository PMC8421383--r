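# Independent oracles and small fixtures shared across the test files.

# shoelace area of a polygon given as an n x 2 matrix of vertices
shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# signed-ring polygon area oracle for eh_section outlines (holes carry -1)
poly_area <- function(rings) sum(vapply(rings, function(r) r$sign * shoelace(r$xy),
                                        numeric(1)))

# number of boundary pixels of a logical region (4-neighbour adjacency);
# used for perimeter-scaled rasterization tolerances
boundary_pixels <- function(mask) {
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  inner <- padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  nb <- padded[1:nrow(mask), 2:(ncol(mask) + 1)] &
        padded[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)] &
        padded[2:(nrow(mask) + 1), 1:ncol(mask)] &
        padded[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  sum(inner & !nb)
}

# fast-rendering phantom spec for unit tests
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(64L, 64L, 8L), noise_sd = 0, seed = 101L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# brute-force negative-pixel EH ratio: explicit double loop over the ROI
naive_eh_ratio <- function(mi2, roi) {
  sl <- mi2$data[, , roi$slice]
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(sl))) for (j in seq_len(ncol(sl))) {
    if (roi$mask[i, j]) {
      den <- den + 1L
      if (sl[i, j] < 0) num <- num + 1L
    }
  }
  list(numerator = num, denominator = den, ratio = num / den)
}

# endolymph fraction of an ROI straight from the label plane
label_fraction <- function(labels, roi) {
  pl <- labels$labels[, , roi$slice]
  mean(pl[roi$mask] %in% ehquant:::endolymph_codes())
}
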