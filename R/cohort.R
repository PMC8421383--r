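# clipped (winsorized) normal draw: values outside (lo, hi) are set to the
# bound, matching the recorded clip bounds of the cohort tables
clip_norm <- function(n, mean, sd, lo = 0.001, hi = 0.999) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Joint saccule/utricle draw under the sum < 1 constraint. The organs share
# the fixed vestibular space, so their fractions are modelled as a bivariate
# normal with negative correlation `rho` (each marginal keeps the published
# mean and SD); pairs violating the simplex constraint after clipping are
# redrawn, up to `max_attempts` rounds, then an error is raised. The
# anticorrelation makes the published marginals jointly feasible: with
# independent draws at the published SDs the constraint would truncate away
# ~16% of the mass and visibly depress both sample means.
draw_organ_pair <- function(n, sacc, utr, rho = -0.8, lo = 0.001, hi = 0.999,
                            max_attempts = 100L) {
  draw <- function(m) {
    z1 <- stats::rnorm(m)
    z2 <- stats::rnorm(m)
    cbind(pmin(pmax(sacc[["mean"]] + sacc[["sd"]] * z1, lo), hi),
          pmin(pmax(utr[["mean"]] +
                    utr[["sd"]] * (rho * z1 + sqrt(1 - rho^2) * z2), lo), hi))
  }
  su <- draw(n)
  bad <- rowSums(su) >= 1
  attempts <- 0L
  while (any(bad)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("unable to draw saccule + utricle fractions with sum < 1 after ",
           max_attempts, " attempts")
    su[bad, ] <- draw(sum(bad))
    bad[bad] <- rowSums(su[bad, , drop = FALSE]) >= 1
  }
  colnames(su) <- c("saccule", "utricle")
  su
}

#' Specification of a synthetic study cohort
#'
#' Describes the groups of a simulated study: how many ears per side class
#' and the distribution (mean, SD) every ground-truth fraction is drawn
#' from. Defaults reproduce the histology study populations: 54 affected
#' ears and 17 healthy-control ears at the published group parameters,
#' including the observed herniation proportions on the affected side.
#'
#' Per-ear fractions are drawn from clipped normal distributions (values
#' outside `clip` are set to the bound). Groups that specify `saccule` and
#' `utricle` distributions draw the two organs jointly under the
#' saccule + utricle < 1 constraint (saccule from its marginal, utricle
#' truncated to the remaining room); groups that specify only a combined
#' `vestibule` distribution draw the combined fraction and split it between
#' the organs at `saccule_share`.
#'
#' @param groups Named list (names are side classes: `affected`,
#'   `unaffected`, `control`). Each group is a list with elements `n`
#'   (ears), `cochlea` = `c(mean, sd)`, either `vestibule` = `c(mean, sd)`
#'   or both `saccule` and `utricle`, optional `canal_ampullary` /
#'   `canal_nonampullary` (named lists per canal of `c(mean, sd)`), and
#'   optional `herniation` probabilities `c(saccular, utricular, both)`.
#' @param saccule_share Fraction of a combined vestibular draw assigned to
#'   the saccule; default is the published saccular:utricular contribution
#'   ratio 0.513 : 0.242.
#' @param organ_correlation Correlation of the latent saccular/utricular
#'   draws in organ-sampling groups, in `[-1, 0]`. The organs compete for
#'   the fixed vestibular space, so their fractions are anticorrelated; the
#'   default -0.8 keeps the published marginals essentially intact under
#'   the saccule + utricle < 1 constraint (independent draws at the
#'   published SDs would violate it ~16% of the time and the redraws would
#'   visibly depress both means).
#' @param clip Lower/upper clip bounds for every fraction draw.
#' @param grid_shape,voxel_size_mm,signal,noise_sd Phantom template passed to
#'   every generated [phantom_spec()].
#' @param seed Master seed; every per-ear draw and per-ear phantom seed
#'   derives from it.
#' @return An object of class `cohort_spec`.
#' @examples
#' cs <- cohort_spec(seed = 7)
#' names(cs$groups)
#' @export
cohort_spec <- function(groups = default_cohort_groups(),
                        saccule_share = 0.513 / (0.513 + 0.242),
                        organ_correlation = -0.8,
                        clip = c(0.001, 0.999),
                        grid_shape = c(128L, 128L, 10L),
                        voxel_size_mm = c(0.5, 0.5, 1.0),
                        signal = signal_model(),
                        noise_sd = 20,
                        seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  if (!all(names(groups) %in% c("affected", "unaffected", "control")))
    stop("group names must be side classes: affected, unaffected, control")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n) || gr$n < 1)
      stop("group '", g, "' needs a positive n")
    for (d in intersect(names(gr), c("cochlea", "vestibule", "saccule", "utricle"))) {
      if (gr[[d]][["sd"]] < 0) stop("SD for '", d, "' in group '", g, "' must be >= 0")
    }
    if (!is.null(gr$herniation) &&
        (any(gr$herniation < 0) || sum(gr$herniation) > 1))
      stop("herniation probabilities in group '", g, "' must lie in [0, 1]")
  }
  if (clip[1] <= 0 || clip[2] >= 1 || clip[1] >= clip[2])
    stop("clip bounds must satisfy 0 < lo < hi < 1")
  if (organ_correlation < -1 || organ_correlation > 0)
    stop("organ_correlation must lie in [-1, 0]")
  structure(list(groups = groups, saccule_share = saccule_share,
                 organ_correlation = organ_correlation, clip = clip,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, signal = signal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_groups <- function() {
  p <- eh_group_params()$histology
  list(
    affected = list(
      n = p$n$affected,
      cochlea = p$cochlea$affected,
      saccule = p$saccule$affected,
      utricle = p$utricle$affected,
      canal_ampullary = p$canal_ampullary$affected,
      canal_nonampullary = p$canal_ampullary$affected,
      herniation = p$herniation$affected),
    control = list(
      n = p$n$control,
      cochlea = p$cochlea$control,
      vestibule = p$vestibule$control,
      canal_ampullary = p$canal_ampullary$unaffected,
      canal_nonampullary = p$canal_ampullary$unaffected,
      herniation = p$herniation$control)
  )
}

#' @rdname cohort_spec
#' @details `mri_cohort_groups()` returns the single-group layout of the MR
#'   imaging cohort: 72 affected ears at the published MRI cochlear and
#'   (combined) vestibular distributions, with the observed canal-extension
#'   proportion split between the organs at the histology ratio.
#' @export
mri_cohort_groups <- function() {
  p <- eh_group_params()
  ext <- p$mri$herniation$affected[["extension"]]
  list(affected = list(
    n = p$mri$n$affected,
    cochlea = p$mri$cochlea$affected,
    vestibule = p$mri$vestibule$affected,
    canal_ampullary = p$histology$canal_ampullary$affected,
    canal_nonampullary = p$histology$canal_ampullary$affected,
    herniation = c(saccular = ext * 15 / 24, utricular = ext * 9 / 24, both = 0)))
}

#' Simulate a cohort of synthetic ears
#'
#' Draws per-ear ground-truth fractions and herniation flags for every group
#' of a [cohort_spec()] and builds one [phantom_spec()] per ear. Fully
#' reproducible from the master seed.
#'
#' @param cohort A [cohort_spec()].
#' @param specs Build the per-ear `phantom_spec` list (set `FALSE` to get
#'   only the table, e.g. for large distribution checks).
#' @return A list with `table` -- a long data.frame with one row per ear and
#'   site (`ear_id`, `side`, `site`, `true_fraction`, `herniation`) -- and
#'   `specs`, a named list of [phantom_spec()] objects (empty if
#'   `specs = FALSE`).
#' @examples
#' sim <- simulate_cohort(cohort_spec(seed = 42), specs = FALSE)
#' head(sim$table)
#' @export
simulate_cohort <- function(cohort, specs = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  lo <- cohort$clip[1]; hi <- cohort$clip[2]
  canal_sites <- as.vector(outer(c("anterior", "lateral", "posterior"),
                                 c("ampullary", "nonampullary"), paste, sep = "_"))

  with_seed(cohort$seed, {
    rows <- list()
    spec_list <- list()
    for (side in names(cohort$groups)) {
      gr <- cohort$groups[[side]]
      n <- as.integer(gr$n)
      coch <- clip_norm(n, gr$cochlea[["mean"]], gr$cochlea[["sd"]], lo, hi)
      if (!is.null(gr$saccule) && !is.null(gr$utricle)) {
        su <- draw_organ_pair(n, gr$saccule, gr$utricle,
                              rho = cohort$organ_correlation, lo = lo, hi = hi)
      } else if (!is.null(gr$vestibule)) {
        comb <- clip_norm(n, gr$vestibule[["mean"]], gr$vestibule[["sd"]], lo, hi)
        su <- cbind(saccule = comb * cohort$saccule_share,
                    utricle = comb * (1 - cohort$saccule_share))
      } else {
        stop("group '", side, "' must specify either saccule+utricle or vestibule")
      }
      canal <- matrix(NA_real_, n, 6, dimnames = list(NULL, canal_sites))
      for (cn in c("anterior", "lateral", "posterior")) {
        pa <- gr$canal_ampullary[[cn]]
        pn <- gr$canal_nonampullary[[cn]]
        if (is.null(pa)) pa <- c(mean = 0.5, sd = 0)
        if (is.null(pn)) pn <- pa
        canal[, paste0(cn, "_ampullary")] <- clip_norm(n, pa[["mean"]], pa[["sd"]], lo, hi)
        canal[, paste0(cn, "_nonampullary")] <- clip_norm(n, pn[["mean"]], pn[["sd"]], lo, hi)
      }
      hp <- gr$herniation
      if (is.null(hp)) hp <- c(saccular = 0, utricular = 0, both = 0)
      hern <- sample(c("saccular", "utricular", "both", "none"), n, replace = TRUE,
                     prob = c(hp[["saccular"]], hp[["utricular"]], hp[["both"]],
                              1 - sum(hp)))
      seeds <- sample.int(.Machine$integer.max - 1L, n)
      ids <- sprintf("%s_%03d", side, seq_len(n))

      frac <- cbind(cochlea = coch, saccule = su[, "saccule"],
                    utricle = su[, "utricle"],
                    vestibule = su[, "saccule"] + su[, "utricle"],
                    canal)
      colnames(frac)[-(1:4)] <- paste0("canal_", canal_sites)
      nsite <- ncol(frac)
      rows[[length(rows) + 1L]] <- data.frame(
        ear_id = rep(ids, each = nsite), side = side,
        site = rep(colnames(frac), n),
        true_fraction = as.vector(t(frac)),
        herniation = rep(hern, each = nsite),
        stringsAsFactors = FALSE)

      for (i in seq_len(n)) {
        if (specs) {
          spec_list[[ids[i]]] <- phantom_spec(
            ear_id = ids[i], side = side,
            grid_shape = cohort$grid_shape,
            voxel_size_mm = cohort$voxel_size_mm,
            cochlea_true_fraction = coch[i],
            saccule_true_fraction = unname(su[i, "saccule"]),
            utricle_true_fraction = unname(su[i, "utricle"]),
            canal_duct_fraction_ampullary = c(
              anterior = unname(canal[i, "anterior_ampullary"]),
              lateral = unname(canal[i, "lateral_ampullary"]),
              posterior = unname(canal[i, "posterior_ampullary"])),
            canal_duct_fraction_nonampullary = c(
              anterior = unname(canal[i, "anterior_nonampullary"]),
              lateral = unname(canal[i, "lateral_nonampullary"]),
              posterior = unname(canal[i, "posterior_nonampullary"])),
            herniation = hern[i],
            signal = cohort$signal,
            noise_sd = cohort$noise_sd,
            seed = seeds[i])
        }
      }
    }
    list(table = do.call(rbind, rows), specs = spec_list)
  })
}
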