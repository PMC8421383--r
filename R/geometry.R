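# Supersampled rasterization of the stylized inner-ear geometry.
#
# All regions are radial/sector constructs (disks, annuli, disk sectors,
# annular sectors), so a label is assigned to a point by a handful of
# comparisons on its polar coordinates. Pixels are rasterized by evaluating
# the label at a 4x4 subpixel grid and taking the majority label, which
# keeps the area bias of every region below about one boundary-pixel row.

RASTER_SS <- 4L

# subpixel center coordinates along one axis, sub index fastest
ss_coords <- function(n, ss = RASTER_SS) {
  offs <- ((seq_len(ss) - 0.5) / ss) - 0.5
  as.vector(t(outer(seq_len(n), offs, "+")))
}

# full supersampled coordinate matrices, dims (nx*ss, ny*ss)
ss_grid <- function(nx, ny, ss = RASTER_SS) {
  xs <- ss_coords(nx, ss)
  ys <- ss_coords(ny, ss)
  list(X = matrix(xs, length(xs), length(ys)),
       Y = matrix(ys, length(xs), length(ys), byrow = TRUE))
}

# majority vote per ss x ss block; ties broken toward the lowest label code
majority_downsample <- function(L, nx, ny, ss = RASTER_SS) {
  codes <- sort(unique(as.vector(L)))
  if (length(codes) == 1L)
    return(matrix(codes, nx, ny))
  best_cnt <- matrix(-1, nx, ny)
  best_lab <- matrix(codes[1], nx, ny)
  for (u in codes) {
    m <- L == u
    dim(m) <- c(ss, nx, ss, ny)
    cnt <- colSums(m, dims = 1)                       # (nx, ss, ny)
    cnt <- colSums(aperm(cnt, c(2L, 1L, 3L)), dims = 1) # (nx, ny)
    upd <- cnt > best_cnt
    best_lab[upd] <- u
    best_cnt[upd] <- cnt[upd]
  }
  storage.mode(best_lab) <- "integer"
  best_lab
}

# angle helpers -------------------------------------------------------------

# absolute angular distance between theta and ref, in [0, pi]
ang_dist <- function(theta, ref) {
  d <- (theta - ref) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# is theta inside the sector starting at `start`, sweeping `width` ccw?
in_sector <- function(theta, start, width) {
  ((theta - start) %% (2 * pi)) < width
}

# plane labellers ------------------------------------------------------------

# Cochlear cross-section: modiolus core + three concentric turn annuli, each
# with a scala-media angular sector covering fraction `f` of the annulus.
cochlea_plane_labels <- function(X, Y, geom, f, modiolus_r) {
  lb <- eh_labels()
  cc <- geom$cochlea
  dx <- X - cc$center[1]
  dy <- Y - cc$center[2]
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx)
  out <- matrix(0L, nrow(X), ncol(X))
  width <- 2 * pi * f
  turns <- list(basal = cc$r_basal, middle = cc$r_middle, apical = cc$r_apical)
  for (tn in names(turns)) {
    ann <- r >= turns[[tn]][1] & r < turns[[tn]][2]
    sm <- ann & in_sector(theta, cc$sm_start[[tn]], width)
    out[ann] <- lb[[paste0("peri_", tn)]]
    out[sm] <- lb[[paste0("scala_media_", tn)]]
  }
  out[r <= modiolus_r] <- lb[["modiolus"]]
  out
}

# Vestibular cross-section: vestibule disk with saccule/utricle disk sectors
# (adjacent at the canal-territory direction so either organ can herniate),
# the lateral-canal ring (annulus with an embedded duct band, drawn only over
# the visible arc), the ampulla on the ring, and an optional herniation
# protrusion into the canal territory.
vestibule_plane_labels <- function(X, Y, geom, spec, ring_coverage_deg = 360,
                                   with_ring = TRUE) {
  lb <- eh_labels()
  vg <- geom$vestibule
  fs <- spec$saccule_true_fraction
  fu <- spec$utricle_true_fraction
  dx <- X - vg$center[1]
  dy <- Y - vg$center[2]
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx)
  out <- matrix(0L, nrow(X), ncol(X))

  if (with_ring) {
    ri <- vg$ring_r[1]; ro <- vg$ring_r[2]
    ring <- r >= ri & r < ro
    if (ring_coverage_deg < 360) {
      # visible arc centered opposite the canal territory
      arc_center <- vg$herniation_angle + pi
      ring <- ring & ang_dist(theta, arc_center) <= (ring_coverage_deg / 2) * pi / 180
    }
    out[ring] <- lb[["canal_peri_lateral"]]
    # membranous duct as a radial band with exact area share of the ring
    d <- spec$canal_duct_fraction_nonampullary[["lateral"]]
    mid2 <- (ri^2 + ro^2) / 2
    half <- d * (ro^2 - ri^2) / 2
    duct <- ring & r >= sqrt(mid2 - half) & r < sqrt(mid2 + half)
    out[duct] <- lb[["canal_duct_lateral"]]
    # ampulla: dilated disk sitting on the ring
    amid <- (ri + ro) / 2
    ax <- vg$center[1] + amid * cos(vg$ampulla_angle)
    ay <- vg$center[2] + amid * sin(vg$ampulla_angle)
    ra <- sqrt((X - ax)^2 + (Y - ay)^2)
    amp <- ra <= vg$ampulla_r
    out[amp] <- lb[["ampulla_peri_lateral"]]
    fa <- spec$canal_duct_fraction_ampullary[["lateral"]]
    out[amp & ra <= vg$ampulla_r * sqrt(fa)] <- lb[["ampulla_duct_lateral"]]
  }

  # vestibule disk: saccule sweeps up to the herniation direction, utricle
  # continues from it, remaining area is vestibular perilymph
  disk <- r <= vg$r
  ha <- vg$herniation_angle
  out[disk] <- lb[["vestibule_peri"]]
  out[disk & in_sector(theta, ha - 2 * pi * fs, 2 * pi * fs)] <- lb[["saccule"]]
  out[disk & in_sector(theta, ha, 2 * pi * fu)] <- lb[["utricle"]]

  # herniation: protrude the flagged organ radially into the canal territory
  if (spec$herniation != "none") {
    p <- vg$protrusion_frac * vg$ring_r[2]
    band <- r > vg$r & r <= vg$r + p
    dw <- vg$territory_halfwidth
    if (spec$herniation %in% c("saccular", "both"))
      out[band & in_sector(theta, ha - dw, dw)] <- lb[["saccule"]]
    if (spec$herniation %in% c("utricular", "both"))
      out[band & in_sector(theta, ha, dw)] <- lb[["utricle"]]
  }
  out
}

# Canal-territory mask: the lateral-canal lumen sector just outside the
# vestibule boundary (with a one-pixel margin so rasterized organ boundaries
# of a non-herniated vestibule cannot leak into it). Evaluated at pixel
# centers on the (nx, ny) grid.
territory_mask_plane <- function(nx, ny, geom) {
  vg <- geom$vestibule
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dx <- X - vg$center[1]
  dy <- Y - vg$center[2]
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx)
  r > vg$r + vg$territory_margin & r <= vg$ring_r[2] &
    ang_dist(theta, vg$herniation_angle) <= vg$territory_halfwidth
}

# Canal cross-section: bony/perilymphatic disk with a concentric duct disk
# whose radius realizes the duct area fraction exactly.
canal_plane_labels <- function(X, Y, center, r_canal, duct_fraction, canal) {
  codes <- canal_codes(canal)
  rr <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  out <- matrix(0L, nrow(X), ncol(X))
  out[rr <= r_canal] <- codes$peri
  out[rr <= r_canal * sqrt(duct_fraction)] <- codes$duct
  out
}

# polygon ground truth -------------------------------------------------------

# polygon approximations of the analytic region boundaries, used as an
# independent area oracle (shoelace) for the rasterized label counts;
# each region is a list of rings with orientation sign (+1 add, -1 hole)
poly_ring <- function(xy, sign = 1) list(xy = xy, sign = sign)

circle_poly <- function(center, r, n = 720) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

annular_sector_poly <- function(center, r0, r1, start, width, n_per_rad = 120) {
  n <- max(8L, ceiling(width * n_per_rad))
  a <- seq(start, start + width, length.out = n)
  outer_arc <- cbind(center[1] + r1 * cos(a), center[2] + r1 * sin(a))
  if (r0 > 0) {
    inner_arc <- cbind(center[1] + r0 * cos(rev(a)), center[2] + r0 * sin(rev(a)))
    rbind(outer_arc, inner_arc)
  } else {
    rbind(outer_arc, matrix(center, 1, 2))
  }
}

annulus_polys <- function(center, r0, r1) {
  list(poly_ring(circle_poly(center, r1), 1),
       poly_ring(circle_poly(center, r0), -1))
}
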