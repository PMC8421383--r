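# evaluate `code` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so generators are reproducible and isolated
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-voxel compartment index (1 bone, 2 perilymph, 3 endolymph) via lookup
compartment_of <- function(labels) {
  lut <- integer(max(eh_labels()) + 1L)
  lut[bone_codes() + 1L] <- 1L
  lut[perilymph_codes() + 1L] <- 2L
  lut[endolymph_codes() + 1L] <- 3L
  out <- lut[labels + 1L]
  dim(out) <- dim(labels)
  out
}

#' Render the three MR contrast volumes of a synthetic ear
#'
#' Builds the label volume of one stylized inner ear (cochlear turns with
#' scala-media sectors, vestibule with saccule and utricle, lateral canal
#' ring with ampulla, optional herniation) and fills the MRC, PPI and PEI
#' contrasts from the spec's signal model plus independent zero-mean Gaussian
#' noise. Rasterization uses 4x supersampling with per-pixel majority voting,
#' so the realized endolymph fraction of every structure matches the spec's
#' ground-truth fraction to within a boundary-row of pixels.
#'
#' Through-plane layout (slice 1 being most inferior): the vestibule and
#' lateral-canal ring occupy five consecutive slices on which the visible arc
#' of the ring grows from 200 deg to a full circle, so the slice-selection
#' rule of [select_vestibule_slice()] has a unique answer; the cochlea
#' occupies five slices on which the modiolus extent peaks at the middle
#' slice, exercising the tie-break of [select_cochlea_slice()].
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `eh_mr_phantom` with elements `mrc`, `ppi`, `pei`
#'   ([eh_volume()]) and `labels` ([eh_label_volume()]).
#' @examples
#' ph <- render_mr_phantom(phantom_spec(grid_shape = c(64, 64, 10), noise_sd = 0))
#' ph$ppi
#' @export
render_mr_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  gs <- spec$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]

  grid <- ss_grid(nx, ny)
  labels <- array(0L, gs)
  territory <- array(FALSE, gs)
  terr2d <- territory_mask_plane(nx, ny, geom)

  # cache rendered planes by configuration key: vestibule slices repeat the
  # same ring coverage and cochlear slices repeat modiolus radii
  cache <- new.env(parent = emptyenv())
  vest_plane <- function(cov) {
    key <- paste0("v", cov)
    if (is.null(cache[[key]])) {
      L <- vestibule_plane_labels(grid$X, grid$Y, geom, spec, ring_coverage_deg = cov)
      cache[[key]] <- majority_downsample(L, nx, ny)
    }
    cache[[key]]
  }
  coch_plane <- function(mod_r) {
    key <- paste0("c", format(mod_r))
    if (is.null(cache[[key]])) {
      L <- cochlea_plane_labels(grid$X, grid$Y, geom,
                                spec$cochlea_true_fraction, mod_r)
      cache[[key]] <- majority_downsample(L, nx, ny)
    }
    cache[[key]]
  }

  for (z in seq_len(nz)) {
    plane <- matrix(0L, nx, ny)
    iv <- match(z, geom$vest_z)
    if (!is.na(iv)) {
      plane <- vest_plane(geom$ring_coverage_deg[iv])
      territory[, , z] <- terr2d
    }
    ic <- match(z, geom$coch_z)
    if (!is.na(ic)) {
      cp <- coch_plane(geom$cochlea$modiolus_profile[ic])
      plane[cp > 0L] <- cp[cp > 0L]  # cochlea and vestibule are disjoint in-plane
    }
    labels[, , z] <- plane
  }

  comp <- compartment_of(labels)
  sm <- spec$signal
  mk <- function(means, tag) {
    v <- array(means[comp], gs)
    if (spec$noise_sd > 0)
      v <- v + array(stats::rnorm(length(v), 0, spec$noise_sd), gs)
    eh_volume(v, spec$voxel_size_mm, tag)
  }
  out <- with_seed(spec$seed, {
    list(mrc = mk(sm$mrc, "MRC"), ppi = mk(sm$ppi, "PPI"), pei = mk(sm$pei, "PEI"))
  })
  out$labels <- eh_label_volume(labels, territory, spec$voxel_size_mm)
  class(out) <- "eh_mr_phantom"
  out
}

#' @export
print.eh_mr_phantom <- function(x, ...) {
  cat("Synthetic MR phantom (MRC / PPI / PEI + labels)\n")
  print(x$mrc); print(x$labels)
  invisible(x)
}

#' Render a labeled histology-style section of a synthetic ear
#'
#' Produces one 2D labeled section image of the requested site, standing in
#' for a representative hematoxylin-eosin slide: the cochlea with three
#' turns and their scala-media subregions, the vestibule with saccule and
#' utricle (plus the lateral-canal ring and territory for herniation
#' assessment), or one semicircular-canal cross-section with its membranous
#' duct (dilated at ampullary sites). Region areas realize the spec's
#' ground-truth fractions to rasterization accuracy, and analytic boundary
#' polygons are attached as an independent area oracle.
#'
#' @param spec A [phantom_spec()].
#' @param site `"cochlea"`, `"vestibule"`, or `"canal"`.
#' @param canal For `site = "canal"`: `"anterior"`, `"lateral"`, `"posterior"`.
#' @param region For `site = "canal"`: `"ampullary"` or `"nonampullary"`.
#' @return An object of class `eh_section`: integer label matrix, logical
#'   canal-territory mask, pixel size (mm), and per-region outline polygons.
#' @examples
#' sec <- render_histo_section(phantom_spec(grid_shape = c(64, 64, 10)), "vestibule")
#' table(sec$labels)[1:3]
#' @export
render_histo_section <- function(spec,
                                 site = c("cochlea", "vestibule", "canal"),
                                 canal = c("anterior", "lateral", "posterior"),
                                 region = c("ampullary", "nonampullary")) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.character(site) && length(site) == 1L &&
      !site %in% c("cochlea", "vestibule", "canal"))
    stop("unknown site '", site, "'")
  site <- match.arg(site)
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  grid <- ss_grid(nx, ny)
  territory <- NULL
  outlines <- list()

  if (site == "cochlea") {
    cc <- geom$cochlea
    L <- cochlea_plane_labels(grid$X, grid$Y, geom,
                              spec$cochlea_true_fraction, cc$modiolus_r_peak)
    f <- spec$cochlea_true_fraction
    turns <- list(basal = cc$r_basal, middle = cc$r_middle, apical = cc$r_apical)
    for (tn in names(turns))
      outlines[[paste0("scala_media_", tn)]] <- list(poly_ring(
        annular_sector_poly(cc$center, turns[[tn]][1], turns[[tn]][2],
                            cc$sm_start[[tn]], 2 * pi * f)))
    outlines$cochlea_fluid <- annulus_polys(cc$center, cc$r_apical[1], cc$r_basal[2])
    outlines$modiolus <- list(poly_ring(circle_poly(cc$center, cc$modiolus_r_peak)))
  } else if (site == "vestibule") {
    vg <- geom$vestibule
    L <- vestibule_plane_labels(grid$X, grid$Y, geom, spec)
    territory <- territory_mask_plane(nx, ny, geom)
    fs <- spec$saccule_true_fraction
    fu <- spec$utricle_true_fraction
    ha <- vg$herniation_angle
    outlines$vestibule <- list(poly_ring(circle_poly(vg$center, vg$r)))
    outlines$saccule <- list(poly_ring(
      annular_sector_poly(vg$center, 0, vg$r, ha - 2 * pi * fs, 2 * pi * fs)))
    outlines$utricle <- list(poly_ring(
      annular_sector_poly(vg$center, 0, vg$r, ha, 2 * pi * fu)))
    p <- vg$protrusion_frac * vg$ring_r[2]
    dw <- vg$territory_halfwidth
    if (spec$herniation %in% c("saccular", "both"))
      outlines$saccule <- c(outlines$saccule, list(poly_ring(
        annular_sector_poly(vg$center, vg$r, vg$r + p, ha - dw, dw))))
    if (spec$herniation %in% c("utricular", "both"))
      outlines$utricle <- c(outlines$utricle, list(poly_ring(
        annular_sector_poly(vg$center, vg$r, vg$r + p, ha, dw))))
  } else {
    canal <- match.arg(canal)
    region <- match.arg(region)
    r_canal <- if (region == "ampullary") geom$canal_section$r_ampullary
               else geom$canal_section$r_nonampullary
    f <- if (region == "ampullary") spec$canal_duct_fraction_ampullary[[canal]]
         else spec$canal_duct_fraction_nonampullary[[canal]]
    center <- c(nx / 2, ny / 2)
    L <- canal_plane_labels(grid$X, grid$Y, center, r_canal, f, canal)
    outlines$cross_section <- list(poly_ring(circle_poly(center, r_canal)))
    outlines$duct <- list(poly_ring(circle_poly(center, r_canal * sqrt(f))))
  }

  labels <- majority_downsample(L, nx, ny)
  if (is.null(territory)) territory <- matrix(FALSE, nx, ny)
  structure(list(labels = labels, territory = territory,
                 pixel_size_mm = spec$voxel_size_mm[1:2],
                 site = site,
                 canal = if (site == "canal") canal else NA_character_,
                 region = if (site == "canal") region else NA_character_,
                 ear_id = spec$ear_id, side = spec$side,
                 herniation = spec$herniation,
                 outlines = outlines),
            class = "eh_section")
}

#' @export
print.eh_section <- function(x, ...) {
  cat(sprintf("eh_section '%s' site=%s%s %s px, pixel %s mm\n",
              x$ear_id, x$site,
              if (!is.na(x$canal)) paste0(" (", x$canal, ", ", x$region, ")") else "",
              paste(dim(x$labels), collapse = "x"),
              paste(x$pixel_size_mm, collapse = "x")))
  invisible(x)
}

#' @describeIn render_histo_section Display a section's label image.
#' @param x An `eh_section`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.eh_section <- function(x, ...) {
  graphics::image(seq_len(nrow(x$labels)), seq_len(ncol(x$labels)),
                  x$labels, asp = 1, xlab = "x (px)", ylab = "y (px)",
                  main = paste("section:", x$site), ...)
  invisible(x)
}
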