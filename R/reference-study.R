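#' Re-run the reference study on synthetic cohorts
#'
#' Generates synthetic cohorts at the published group parameters
#' ([eh_group_params()]) and pushes them through the full measurement
#' pipeline, reproducing the study's headline quantities with known ground
#' truth:
#' \itemize{
#'   \item histology cohort (54 affected + 17 control ears): section
#'     rendering and area morphometry for the cochlea, saccule, utricle and
#'     ampullary anterior canal;
#'   \item a combined-vestibular affected cohort (n = 54) drawn at the
#'     published vestibular distribution and split between the organs at the
#'     published contribution ratio;
#'   \item MRI cohort (72 affected ears): volume rendering, HYDROPS and
#'     HYDROPS-Mi2 composition, rule-based slice selection and
#'     negative-pixel counting for cochlea and vestibule;
#'   \item repeated two-group comparisons (20 replicate seeds) for affected
#'     vs. control cochlear ratios and saccular vs. utricular ratios, each
#'     reported as the largest p-value observed.
#' }
#'
#' @param seed Master seed; all cohorts and replicate draws derive from it.
#' @param grid_shape Phantom grid used for every rendered ear.
#' @param n_comparison_seeds Number of replicate seeds for the p-value
#'   bounds.
#' @param n_replicates Number of independent replicate cohorts averaged for
#'   each mean target. Each replicate is a fresh cohort at the published
#'   group size; replication leaves every estimand unchanged while shrinking
#'   its Monte-Carlo standard error by `1/sqrt(n_replicates)`.
#' @return A named list; each element is a list with `value` (the simulated
#'   quantity on the scale the study reports) and `n` (the per-cohort group
#'   size, i.e. the published problem size).
#' @examples
#' \dontrun{
#' res <- run_reference_study(seed = 1)
#' res$histology_cochlea_affected_mean
#' }
#' @export
run_reference_study <- function(seed = 1L, grid_shape = c(128L, 128L, 10L),
                                n_comparison_seeds = 20L, n_replicates = 1L) {
  p <- eh_group_params()
  sub <- with_seed(seed, matrix(sample.int(2^30, 4 * n_replicates),
                                nrow = n_replicates))
  pick <- function(d, site, side, method) {
    d$ratio[d$site == site & d$side == side & d$method == method]
  }

  coch_aff <- coch_ctl <- sac_aff <- utr_aff <- canal_aff <- numeric(0)
  vest_aff <- mri_coch <- mri_vest <- numeric(0)
  for (r in seq_len(n_replicates)) {
    # --- histology cohort: per-organ sampling -------------------------------
    sim_h <- simulate_cohort(cohort_spec(groups = default_cohort_groups(),
                                         grid_shape = grid_shape,
                                         seed = sub[r, 1]))
    res_h <- measure_cohort(sim_h, "histology",
                            sites = c("cochlea", "vestibule", "canal"),
                            canals = "anterior", regions = "ampullary")
    mh <- res_h$measurements
    coch_aff <- c(coch_aff, pick(mh, "cochlea", "affected", "histo_area"))
    coch_ctl <- c(coch_ctl, pick(mh, "cochlea", "control", "histo_area"))
    sac_aff <- c(sac_aff, pick(mh, "saccule", "affected", "histo_area"))
    utr_aff <- c(utr_aff, pick(mh, "utricle", "affected", "histo_area"))
    canal_aff <- c(canal_aff,
                   pick(mh, "canal_anterior_ampullary", "affected", "histo_area"))

    # --- combined-vestibular affected cohort --------------------------------
    vest_groups <- list(affected = list(
      n = p$histology$n$affected,
      cochlea = p$histology$cochlea$affected,
      vestibule = p$histology$vestibule$affected,
      herniation = p$histology$herniation$affected))
    sim_v <- simulate_cohort(cohort_spec(groups = vest_groups,
                                         grid_shape = grid_shape,
                                         seed = sub[r, 2]))
    res_v <- measure_cohort(sim_v, "histology", sites = "vestibule")
    vest_aff <- c(vest_aff,
                  pick(res_v$measurements, "vestibule", "affected", "histo_area"))

    # --- MRI cohort ----------------------------------------------------------
    sim_m <- simulate_cohort(cohort_spec(groups = mri_cohort_groups(),
                                         grid_shape = grid_shape,
                                         seed = sub[r, 3]))
    res_m <- measure_cohort(sim_m, "mri")
    mm <- res_m$measurements
    mri_coch <- c(mri_coch, pick(mm, "cochlea", "affected", "mri_negative_pixel"))
    mri_vest <- c(mri_vest, pick(mm, "vestibule", "affected", "mri_negative_pixel"))
  }

  # --- replicated group comparisons ------------------------------------------
  rep_seeds <- with_seed(sub[1, 4], sample.int(2^30, n_comparison_seeds))
  p_coch <- vapply(rep_seeds, function(s) with_seed(s, {
    a <- clip_norm(p$histology$n$affected,
                   p$histology$cochlea$affected[["mean"]],
                   p$histology$cochlea$affected[["sd"]])
    b <- clip_norm(p$histology$n$control,
                   p$histology$cochlea$control[["mean"]],
                   p$histology$cochlea$control[["sd"]])
    compare_groups(a, b, labels = c("affected", "control"))$p_value
  }), numeric(1))
  p_su <- vapply(rep_seeds, function(s) with_seed(s + 1L, {
    a <- clip_norm(p$histology$n$affected,
                   p$histology$saccule$affected[["mean"]],
                   p$histology$saccule$affected[["sd"]])
    b <- clip_norm(p$histology$n$affected,
                   p$histology$utricle$affected[["mean"]],
                   p$histology$utricle$affected[["sd"]])
    compare_groups(a, b, labels = c("saccule", "utricle"))$p_value
  }), numeric(1))

  val <- function(x, n) list(value = unname(x), n = as.integer(n))
  n_aff <- p$histology$n$affected
  list(
    histology_cochlea_affected_mean = val(mean(coch_aff), n_aff),
    histology_cochlea_control_mean = val(mean(coch_ctl), p$histology$n$control),
    histology_vestibule_affected_mean = val(mean(vest_aff), n_aff),
    mri_cochlea_affected_mean = val(mean(mri_coch), p$mri$n$affected),
    mri_vestibule_affected_mean = val(mean(mri_vest), p$mri$n$affected),
    histology_saccule_affected_mean = val(mean(sac_aff), n_aff),
    histology_utricle_affected_mean = val(mean(utr_aff), n_aff),
    cochlea_affected_vs_control_max_p = val(max(p_coch), length(p_coch)),
    saccule_vs_utricle_max_p = val(max(p_su), length(p_su)),
    canal_anterior_ampullary_affected_mean = val(mean(canal_aff), n_aff)
  )
}
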