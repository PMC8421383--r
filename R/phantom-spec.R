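#' Parametric description of one synthetic inner ear
#'
#' A `phantom_spec` fully determines one synthetic ear: grid, voxel size,
#' ground-truth endolymph-area fractions for every measured structure, the MR
#' signal model, the noise level, herniation of the otolithic organs into the
#' lateral semicircular canal, and the random seed. [render_mr_phantom()] and
#' [render_histo_section()] consume it.
#'
#' Fraction semantics mirror the measurement definitions: the cochlear
#' fraction is the scala-media share of the total cochlear fluid
#' cross-section on the representative slice; saccular/utricular fractions
#' are shares of the entire vestibule area; canal fractions are the
#' endolymphatic-duct share of the canal cross-section.
#'
#' @param ear_id Character identifier.
#' @param side One of `"affected"`, `"unaffected"`, `"control"`.
#' @param grid_shape Integer vector of 3 positive voxel counts
#'   (in-plane x, in-plane y, slices). In-plane dimensions must be >= 64 and
#'   at least 8 slices are required so every structure has room.
#' @param voxel_size_mm Numeric vector of 3 positive voxel edge lengths (mm).
#' @param cochlea_true_fraction Scala-media share of the cochlear fluid
#'   cross-section, in (0, 1).
#' @param saccule_true_fraction,utricle_true_fraction Organ shares of the
#'   vestibule area, each in (0, 1) with sum < 1.
#' @param canal_duct_fraction_ampullary,canal_duct_fraction_nonampullary
#'   Named numeric vectors (`anterior`, `lateral`, `posterior`) of duct
#'   area fractions in (0, 1).
#' @param herniation One of `"none"`, `"saccular"`, `"utricular"`, `"both"`:
#'   whether an otolithic organ protrudes into the lateral-canal territory.
#' @param signal An [signal_model()] object.
#' @param noise_sd Standard deviation of the additive Gaussian noise on each
#'   contrast (same arbitrary units as the signal model); `0` disables noise.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(saccule_true_fraction = 0.5, utricle_true_fraction = 0.25)
#' spec$saccule_true_fraction
#' @export
phantom_spec <- function(ear_id = "ear01",
                         side = c("affected", "unaffected", "control"),
                         grid_shape = c(128L, 128L, 10L),
                         voxel_size_mm = c(0.5, 0.5, 1.0),
                         cochlea_true_fraction = 0.314,
                         saccule_true_fraction = 0.513,
                         utricle_true_fraction = 0.242,
                         canal_duct_fraction_ampullary =
                           c(anterior = 0.565, lateral = 0.511, posterior = 0.518),
                         canal_duct_fraction_nonampullary =
                           c(anterior = 0.565, lateral = 0.511, posterior = 0.518),
                         herniation = c("none", "saccular", "utricular", "both"),
                         signal = signal_model(),
                         noise_sd = 20,
                         seed = 1L) {
  side <- match.arg(side)
  herniation <- match.arg(herniation)
  spec <- structure(
    list(ear_id = as.character(ear_id),
         side = side,
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         cochlea_true_fraction = cochlea_true_fraction,
         saccule_true_fraction = saccule_true_fraction,
         utricle_true_fraction = utricle_true_fraction,
         canal_duct_fraction_ampullary = canal_duct_fraction_ampullary,
         canal_duct_fraction_nonampullary = canal_duct_fraction_nonampullary,
         herniation = herniation,
         signal = signal,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

in_unit <- function(x) is.numeric(x) && all(x > 0) && all(x < 1)

validate_phantom_spec <- function(spec) {
  gs <- spec$grid_shape
  if (length(gs) != 3L || any(gs <= 0L))
    stop("grid_shape must be 3 positive integers")
  if (length(spec$voxel_size_mm) != 3L || any(spec$voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  if (!in_unit(spec$cochlea_true_fraction))
    stop("cochlea_true_fraction must be strictly in (0, 1)")
  if (!in_unit(spec$saccule_true_fraction) || !in_unit(spec$utricle_true_fraction))
    stop("saccule and utricle fractions must be strictly in (0, 1)")
  if (spec$saccule_true_fraction + spec$utricle_true_fraction >= 1)
    stop("saccule_true_fraction + utricle_true_fraction must be < 1")
  for (nm in c("canal_duct_fraction_ampullary", "canal_duct_fraction_nonampullary")) {
    v <- spec[[nm]]
    if (!all(c("anterior", "lateral", "posterior") %in% names(v)) || !in_unit(v))
      stop("'", nm, "' must name anterior/lateral/posterior fractions in (0, 1)")
  }
  if (!is.numeric(spec$noise_sd) || spec$noise_sd < 0)
    stop("noise_sd must be a nonnegative real")
  validate_signal_model(spec$signal)
  phantom_geometry(spec)  # errors if any structure is clipped by the grid
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec '%s' (%s side), grid %s, voxel %s mm\n",
              x$ear_id, x$side, paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  cat(sprintf("  cochlea %.3f | saccule %.3f + utricle %.3f | herniation %s | noise_sd %g\n",
              x$cochlea_true_fraction, x$saccule_true_fraction,
              x$utricle_true_fraction, x$herniation, x$noise_sd))
  invisible(x)
}

# In-plane and through-plane layout, in voxel units ------------------------
#
# The anatomy is deliberately stylized: cochlear turns are concentric annuli
# around a modiolus core (scala media as an angular sector of each annulus),
# the vestibule is a disk holding the saccule and utricle as disk sectors,
# and the lateral canal is an annular ring with an ampullary dilation.
# Sector-based regions make every ground-truth area fraction exact by
# construction (a sector's share of a disk or annulus equals its angular
# share), which is the property the measurements validate.
phantom_geometry <- function(spec) {
  gs <- spec$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  if (nx < 64 || ny < 64)
    stop("grid too small: in-plane dimensions must be >= 64 voxels")
  if (nz < 8)
    stop("grid too small: at least 8 slices are required")
  m <- min(nx, ny) / 128

  # Centers carry sub-pixel offsets and sector boundaries sit at generic
  # angles so that no region edge aligns with pixel-center rows or columns:
  # an axis-aligned edge makes every boundary pixel an exact 8/8
  # supersampling tie, which the deterministic tie-break would turn into a
  # systematic area bias of a full boundary row.
  g <- list(
    scale = m,
    cochlea = list(
      center = c(0.28 * nx + 0.31, 0.5 * ny + 0.17),
      # annulus radii: apical innermost, basal outermost
      r_apical = c(6, 12) * m,
      r_middle = c(12, 19) * m,
      r_basal  = c(19, 26) * m,
      modiolus_r_peak = 4.5 * m,
      modiolus_profile = c(2.5, 3.5, 4.5, 3.5, 2.5) * m,
      # scala media sector start angles per turn (radians)
      sm_start = c(basal = -pi / 2 + 0.13, middle = pi / 6 + 0.07,
                   apical = 5 * pi / 6 + 0.11)
    ),
    vestibule = list(
      center = c(0.70 * nx + 0.37, 0.5 * ny + 0.23),
      r = 15 * m,
      ring_r = c(18.5, 22.5) * m,      # lateral canal ring annulus
      ampulla_angle = 5 * pi / 4,      # position of ampulla on the ring
      ampulla_r = 4.5 * m,
      herniation_angle = 0.4,          # canal-territory direction (radians)
      territory_halfwidth = 20 * pi / 180,
      territory_margin = 1,            # px gap beyond vestibule boundary
      protrusion_frac = 0.2            # of the outer ring radius
    ),
    canal_section = list(r_ampullary = 23 * m, r_nonampullary = 15 * m)
  )

  # partial-arc visibility schedule for the lateral canal ring (degrees,
  # centered opposite the canal territory); indexed within vestibule slices
  nvest <- 5L
  ncoch <- 5L
  vest_z <- seq.int(max(2L, round(0.25 * nz)), length.out = nvest)
  coch_z <- seq.int(min(nz - ncoch, vest_z[1] + 2L), length.out = ncoch)
  if (max(vest_z) > nz)
    stop("vestibule clipped by grid: too few slices")
  if (max(coch_z) > nz || min(coch_z) < 1L)
    stop("cochlea clipped by grid: too few slices")
  g$vest_z <- vest_z
  g$coch_z <- coch_z
  g$ring_coverage_deg <- c(200, 250, 360, 360, 360)

  # clipping checks: bounding box of each structure vs. the grid
  check_extent <- function(center, radius, what) {
    if (center[1] - radius < 0.5 || center[1] + radius > nx + 0.5 ||
        center[2] - radius < 0.5 || center[2] + radius > ny + 0.5)
      stop(what, " clipped by grid (extent ", round(2 * radius, 1),
           " voxels at center ", paste(round(center, 1), collapse = ","),
           " does not fit ", nx, "x", ny, ")")
  }
  check_extent(g$cochlea$center, g$cochlea$r_basal[2], "cochlea")
  check_extent(g$vestibule$center,
               mean(g$vestibule$ring_r) + g$vestibule$ampulla_r,
               "lateral canal ring")
  g
}
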