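#' Label vocabulary for phantom anatomy
#'
#' Integer codes used in [render_mr_phantom()] label volumes and
#' [render_histo_section()] section images. Codes are grouped by compartment
#' so that membership tests (endolymph vs. perilymph, per-turn, per-canal)
#' stay cheap integer comparisons.
#'
#' @return Named integer vector mapping label names to codes.
#' @examples
#' eh_labels()[["saccule"]]
#' @export
eh_labels <- function() {
  c(
    background        = 0L,
    modiolus          = 1L,
    # cochlear turns: scala media (endolymph) 11..13, perilymphatic scalae 21..23
    scala_media_basal  = 11L,
    scala_media_middle = 12L,
    scala_media_apical = 13L,
    peri_basal         = 21L,
    peri_middle        = 22L,
    peri_apical        = 23L,
    # vestibule
    vestibule_peri     = 30L,
    saccule            = 31L,
    utricle            = 32L,
    # semicircular canal cross-sections: perilymph 41..43, endolymphatic duct 51..53
    canal_peri_anterior  = 41L,
    canal_peri_lateral   = 42L,
    canal_peri_posterior = 43L,
    canal_duct_anterior  = 51L,
    canal_duct_lateral   = 52L,
    canal_duct_posterior = 53L,
    # ampulla of the lateral canal (perilymph + duct), excluded from the
    # vestibular ROI by the slice-selection rule
    ampulla_peri_lateral = 62L,
    ampulla_duct_lateral = 72L
  )
}

# compartment membership helpers ------------------------------------------

endolymph_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("scala_media_basal", "scala_media_middle", "scala_media_apical",
              "saccule", "utricle",
              "canal_duct_anterior", "canal_duct_lateral", "canal_duct_posterior",
              "ampulla_duct_lateral")])
}

perilymph_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("peri_basal", "peri_middle", "peri_apical", "vestibule_peri",
              "canal_peri_anterior", "canal_peri_lateral", "canal_peri_posterior",
              "ampulla_peri_lateral")])
}

bone_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("background", "modiolus")])
}

cochlea_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("scala_media_basal", "scala_media_middle", "scala_media_apical",
              "peri_basal", "peri_middle", "peri_apical")])
}

turn_codes <- function(turn = c("basal", "middle", "apical")) {
  turn <- match.arg(turn)
  lb <- eh_labels()
  unname(lb[paste0(c("scala_media_", "peri_"), turn)])
}

vestibule_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("vestibule_peri", "saccule", "utricle")])
}

lscc_ring_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("canal_peri_lateral", "canal_duct_lateral")])
}

ampulla_codes <- function() {
  lb <- eh_labels()
  unname(lb[c("ampulla_peri_lateral", "ampulla_duct_lateral")])
}

canal_codes <- function(canal = c("anterior", "lateral", "posterior")) {
  canal <- match.arg(canal)
  lb <- eh_labels()
  list(peri = unname(lb[paste0("canal_peri_", canal)]),
       duct = unname(lb[paste0("canal_duct_", canal)]))
}
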