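# analytic mask builders -----------------------------------------------------

# a 1-degree bin at radius r covers ~r*pi/180 pixels of arc, so analytic
# fixtures for 1-degree binning need a dense, thick ring (radius >> 57 px)
annulus_mask <- function(n = 192, center = c(96.5, 96.5), r0 = 62, r1 = 90,
                         deg_lo = 0, deg_hi = 360) {
  x <- matrix(seq_len(n), n, n); y <- t(x)
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  th <- (atan2(y - center[2], x - center[1]) * 180 / pi) %% 360
  r >= r0 & r <= r1 & th >= deg_lo & th <= deg_hi
}

test_that("arc coverage matches analytic arcs", {
  full <- annulus_mask()
  expect_equal(arc_coverage(full)$degrees, 360)
  half <- annulus_mask(deg_lo = 0, deg_hi = 180)
  cov <- arc_coverage(half, center = c(96.5, 96.5))
  expect_lt(abs(cov$degrees - 180), 2)  # within a couple of 1-degree bins
  expect_equal(arc_coverage(matrix(FALSE, 8, 8))$degrees, 0)
})

test_that("arc coverage is monotone under union and stable under rotation", {
  a <- annulus_mask(deg_lo = 10, deg_hi = 120)
  b <- annulus_mask(deg_lo = 200, deg_hi = 290)
  c0 <- c(96.5, 96.5)
  cov_u <- arc_coverage(a | b, center = c0)$degrees
  expect_gte(cov_u, max(arc_coverage(a, center = c0)$degrees,
                        arc_coverage(b, center = c0)$degrees))
  # rotating the mask by 90 degrees about the center is an exact grid motion
  rot <- t(a)[, rev(seq_len(192))]  # (x,y) -> (y, n+1-x)
  expect_lt(abs(arc_coverage(rot, center = c0)$degrees -
                arc_coverage(a, center = c0)$degrees), 1.5)
})

# synthetic label volumes for the slice-selection rules -----------------------

# each slice's ring is an arc over the given degree window; the windows of a
# volume should jointly cover the circle so that the projected-ring centroid
# sits at the true ring center
ring_label_volume <- function(windows, vest = TRUE, ampulla = TRUE) {
  lb <- eh_labels()
  n <- 64L
  ctr <- c(32.5, 32.5)
  arr <- array(0L, c(n, n, length(windows)))
  for (z in seq_along(windows)) {
    pl <- matrix(0L, n, n)
    w <- windows[[z]]
    if (w[2] > w[1])
      pl[annulus_mask(n, center = ctr, r0 = 19, r1 = 23,
                      deg_lo = w[1], deg_hi = w[2])] <-
        lb[["canal_peri_lateral"]]
    if (vest) {
      pl[annulus_mask(n, center = ctr, r0 = 0, r1 = 10)] <-
        lb[["vestibule_peri"]]
      if (ampulla)
        pl[annulus_mask(n, center = c(32.5 + 9, 32.5), r0 = 0, r1 = 3)] <-
          lb[["ampulla_peri_lateral"]]
    }
    arr[, , z] <- pl
  }
  eh_label_volume(arr)
}

# the adaptive bin width the selector documents: about twice the angle one
# pixel subtends at the ring's median radius (recomputed independently here)
ring_bin_deg <- function(lv) {
  ring3d <- lv$labels %in% ehquant:::lscc_ring_codes()
  dim(ring3d) <- dim(lv$labels)
  idx <- which(apply(ring3d, c(1, 2), any), arr.ind = TRUE)
  ctr <- colMeans(idx)
  r_med <- median(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  max(1, ceiling(2 * (180 / pi) / r_med))
}

test_that("the vestibular slice rule takes the lowest slice above 240 degrees", {
  lv <- ring_label_volume(list(c(0, 200), c(0, 250), c(0, 360), c(0, 360)))
  # brute-force oracle: coverage slice by slice around the projected centroid
  ring3d <- lv$labels == eh_labels()[["canal_peri_lateral"]]
  dim(ring3d) <- dim(lv$labels)
  idx <- which(apply(ring3d, c(1, 2), any), arr.ind = TRUE)
  ctr <- colMeans(idx)
  covs <- vapply(1:4, function(z)
    arc_coverage(ring3d[, , z], center = ctr,
                 bin_deg = ring_bin_deg(lv))$degrees, numeric(1))
  expect_identical(min(which(covs > 240)), 2L)
  sel <- select_vestibule_slice(lv)
  expect_identical(sel$slice, 2L)
  # the returned ROI excludes every ampulla pixel
  amp <- lv$labels[, , 2] %in% ehquant:::ampulla_codes()
  expect_identical(sum(sel$roi$mask & amp), 0L)
  expect_gt(sum(sel$roi$mask), 0)
})

test_that("the 240-degree criterion is strict and failure is an error", {
  # two sub-threshold arcs whose union covers the circle (centroid stays put)
  low <- ring_label_volume(list(c(0, 200), c(160, 360)))
  expect_error(select_vestibule_slice(low), "no qualifying vestibular slice")
  # a complete ring covers exactly 360 degrees: not > 360
  expect_error(select_vestibule_slice(ring_label_volume(list(c(0, 360))),
                                      min_arc_deg = 360),
               "no qualifying vestibular slice")
})

test_that("cochlear slice selection maximizes the modiolus among full-turn slices", {
  ph <- render_mr_phantom(small_spec())
  # brute-force oracle over per-slice label counts
  lb <- eh_labels()
  nz <- dim(ph$labels$labels)[3]
  has_all <- vapply(seq_len(nz), function(z) {
    pl <- ph$labels$labels[, , z]
    all(vapply(c("basal", "middle", "apical"),
               function(tn) any(pl %in% ehquant:::turn_codes(tn)), logical(1)))
  }, logical(1))
  mod <- vapply(seq_len(nz), function(z)
    sum(ph$labels$labels[, , z] == lb[["modiolus"]]), numeric(1))
  cand <- which(has_all)
  expect_gt(length(cand), 1)  # the rule's tie-break must actually engage
  expect_identical(select_cochlea_slice(ph$labels), cand[which.max(mod[cand])])
})

test_that("a unique full-turn slice is returned directly; absence is an error", {
  lb <- eh_labels()
  arr <- array(0L, c(64, 64, 4))
  pl <- matrix(0L, 64, 64)
  ctr <- c(32.5, 32.5)
  pl[annulus_mask(64, center = ctr, r0 = 15, r1 = 20)] <- lb[["peri_basal"]]
  pl[annulus_mask(64, center = ctr, r0 = 10, r1 = 15)] <- lb[["peri_middle"]]
  pl[annulus_mask(64, center = ctr, r0 = 5, r1 = 10)] <- lb[["peri_apical"]]
  arr[, , 3] <- pl
  expect_identical(select_cochlea_slice(eh_label_volume(arr)), 3L)
  arr[, , 3][arr[, , 3] == lb[["peri_apical"]]] <- 0L  # no apical turn anywhere
  expect_error(select_cochlea_slice(eh_label_volume(arr)),
               "no representative cochlear slice")
})
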