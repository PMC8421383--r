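#' Full MRI measurement pipeline for one synthetic ear
#'
#' Runs the complete imaging chain on one [phantom_spec()]: render the three
#' contrasts, compose HYDROPS (PPI - PEI) and HYDROPS-Mi2 (HYDROPS x MRC),
#' select the representative cochlear and vestibular slices by the rule
#' engine, and measure both EH ratios by negative-pixel counting.
#'
#' @param spec A [phantom_spec()].
#' @param sites Which ROIs to measure.
#' @return A list with `measurements` (list of [eh_measurement()]),
#'   `herniation` ([detect_herniation()] on the label volume), and the
#'   selected `slices`.
#' @export
measure_ear_mri <- function(spec, sites = c("cochlea", "vestibule")) {
  sites <- match.arg(sites, several.ok = TRUE)
  ph <- render_mr_phantom(spec)
  mi2 <- compose_mi2(compose_hydrops(ph$ppi, ph$pei), ph$mrc)
  out <- list()
  slices <- list()
  if ("cochlea" %in% sites) {
    z <- select_cochlea_slice(ph$labels)
    out$cochlea <- eh_ratio_mri(mi2, cochlea_roi(ph$labels, z),
                                side = spec$side, ear_id = spec$ear_id)
    slices$cochlea <- z
  }
  if ("vestibule" %in% sites) {
    sel <- select_vestibule_slice(ph$labels)
    out$vestibule <- eh_ratio_mri(mi2, sel$roi,
                                  side = spec$side, ear_id = spec$ear_id)
    slices$vestibule <- sel$slice
  }
  list(measurements = out, herniation = detect_herniation(ph$labels),
       slices = slices)
}

#' Full histology measurement pipeline for one synthetic ear
#'
#' Renders the requested histology-style sections of one ear and measures
#' every area ratio: cochlear scala-media ratio, vestibular
#' combined/saccular/utricular ratios (with a herniation call on the
#' vestibule section), and canal duct ratios.
#'
#' @param spec A [phantom_spec()].
#' @param sites Subset of `"cochlea"`, `"vestibule"`, `"canal"`.
#' @param canals,regions For canal sites, which cross-sections to measure.
#' @return A list with `measurements` (named list of [eh_measurement()]) and
#'   `herniation` (a [detect_herniation()] call, or `NULL` when the
#'   vestibule was not rendered).
#' @export
measure_ear_histo <- function(spec, sites = c("cochlea", "vestibule"),
                              canals = "anterior", regions = "ampullary") {
  sites <- match.arg(sites, c("cochlea", "vestibule", "canal"),
                     several.ok = TRUE)
  out <- list()
  hern <- NULL
  if ("cochlea" %in% sites)
    out$cochlea <- histo_cochlea_ratio(render_histo_section(spec, "cochlea"))
  if ("vestibule" %in% sites) {
    sec <- render_histo_section(spec, "vestibule")
    vr <- histo_vestibule_ratios(sec)
    out$vestibule <- vr$combined
    out$saccule <- vr$saccular
    out$utricle <- vr$utricular
    hern <- detect_herniation(sec)
  }
  if ("canal" %in% sites) {
    for (cn in canals) for (rg in regions) {
      sec <- render_histo_section(spec, "canal", canal = cn, region = rg)
      out[[paste("canal", cn, rg, sep = "_")]] <- histo_canal_ratio(sec)
    }
  }
  list(measurements = out, herniation = hern)
}

#' Measure a whole simulated cohort
#'
#' Applies [measure_ear_histo()] or [measure_ear_mri()] to every ear of a
#' [simulate_cohort()] result and collects the measurements into a long
#' table plus a table of herniation calls.
#'
#' @param sim Result of [simulate_cohort()] (with specs).
#' @param modality `"histology"` or `"mri"`.
#' @param ... Passed to the per-ear measurement function.
#' @return A list with `measurements` (data.frame: ear_id, site, side,
#'   method, numerator, denominator, ratio) and `calls` (data.frame: ear_id,
#'   side, call).
#' @export
measure_cohort <- function(sim, modality = c("histology", "mri"), ...) {
  modality <- match.arg(modality)
  stopifnot(length(sim$specs) > 0)
  meas <- list()
  calls <- list()
  for (spec in sim$specs) {
    res <- if (modality == "histology") measure_ear_histo(spec, ...)
           else measure_ear_mri(spec, ...)
    meas[[length(meas) + 1L]] <- measurements_table(res$measurements)
    if (!is.null(res$herniation))
      calls[[length(calls) + 1L]] <- data.frame(
        ear_id = spec$ear_id, side = spec$side, call = res$herniation$call,
        stringsAsFactors = FALSE)
  }
  list(measurements = do.call(rbind, meas),
       calls = if (length(calls)) do.call(rbind, calls) else NULL)
}
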