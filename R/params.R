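#' Reference group parameters for endolymphatic-hydrops ratios
#'
#' Group means and standard deviations of EH ratios reported for temporal-bone
#' histology (affected Meniere's-disease ears, n = 54; healthy-control ears,
#' n = 17) and for gadolinium-enhanced inner-ear MRI (affected ears of
#' unilateral definite Meniere's disease, n = 72). These parameters drive the
#' default synthetic cohorts, so that simulated studies reproduce the
#' statistical structure of the source populations.
#'
#' Semicircular-canal entries are duct/cross-section area fractions at the
#' ampullary and non-ampullary regions. Published values exist for the
#' ampullary region of each canal on the affected and unaffected sides; the
#' non-ampullary distributions were reported as indistinguishable from the
#' ampullary ones, so the same parameters are reused there.
#'
#' Herniation probabilities encode the observed extension of the otolithic
#' organs into the lateral semicircular canal among affected ears
#' (saccular 15/54, utricular 9/54, none otherwise).
#'
#' @return A nested list of numeric parameters; each distribution is a
#'   `c(mean, sd)` pair.
#' @examples
#' eh_group_params()$histology$cochlea$affected
#' @export
eh_group_params <- function() {
  list(
    histology = list(
      n = list(affected = 54L, control = 17L),
      cochlea   = list(affected = c(mean = 0.314, sd = 0.118),
                       control  = c(mean = 0.064, sd = 0.022)),
      vestibule = list(affected = c(mean = 0.757, sd = 0.205),
                       control  = c(mean = 0.289, sd = 0.062)),
      saccule   = list(affected = c(mean = 0.513, sd = 0.214)),
      utricle   = list(affected = c(mean = 0.242, sd = 0.124)),
      canal_ampullary = list(
        affected   = list(anterior  = c(mean = 0.565, sd = 0.096),
                          lateral   = c(mean = 0.511, sd = 0.158),
                          posterior = c(mean = 0.518, sd = 0.068)),
        unaffected = list(anterior  = c(mean = 0.515, sd = 0.050),
                          lateral   = c(mean = 0.456, sd = 0.092),
                          posterior = c(mean = 0.491, sd = 0.080))
      ),
      herniation = list(affected = c(saccular = 15 / 54, utricular = 9 / 54,
                                     both = 0),
                        control  = c(saccular = 0, utricular = 0, both = 0))
    ),
    mri = list(
      n = list(affected = 72L),
      cochlea   = list(affected = c(mean = 0.372, sd = 0.164)),
      vestibule = list(affected = c(mean = 0.533, sd = 0.250)),
      herniation = list(affected = c(extension = 29 / 72))
    )
  )
}
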