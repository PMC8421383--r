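#' Phenomenological MR signal model for the three inner-ear contrasts
#'
#' Mean signal intensity (arbitrary units) of each tissue compartment on the
#' three acquisitions used for hydrops imaging:
#' \describe{
#'   \item{MRC}{heavily T2-weighted cisternography -- all fluid bright,
#'     bone/background dark.}
#'   \item{PPI}{positive perilymph image (3D-FLAIR) -- enhanced perilymph
#'     bright, endolymph dark.}
#'   \item{PEI}{positive endolymph image (3D-IR) -- reversed contrast.}
#' }
#' The model is phenomenological: the pipeline only ever uses the sign of the
#' PPI - PEI subtraction, so compartment means and their ordering are what
#' matters, not pulse-sequence physics.
#'
#' @param mrc,ppi,pei Named numeric vectors with elements `bone`, `perilymph`,
#'   `endolymph` giving the mean intensity of each compartment.
#' @return An object of class `eh_signal_model`.
#' @details The constructor enforces the contrast logic of the acquisition
#'   scheme: perilymph must be positive and endolymph negative after the
#'   PPI - PEI subtraction, and fluid must be brighter than bone on MRC.
#' @examples
#' sm <- signal_model()
#' sm$ppi[["perilymph"]] - sm$pei[["perilymph"]] # > 0
#' @export
signal_model <- function(mrc = c(bone = 0, perilymph = 800, endolymph = 800),
                         ppi = c(bone = 0, perilymph = 500, endolymph = 100),
                         pei = c(bone = 0, perilymph = 100, endolymph = 500)) {
  need <- c("bone", "perilymph", "endolymph")
  for (nm in c("mrc", "ppi", "pei")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(need %in% names(v))) {
      stop("'", nm, "' must be a named numeric vector with elements ",
           paste(need, collapse = ", "))
    }
  }
  sm <- structure(list(mrc = mrc[need], ppi = ppi[need], pei = pei[need]),
                  class = "eh_signal_model")
  validate_signal_model(sm)
  sm
}

validate_signal_model <- function(sm) {
  if (!(sm$ppi[["perilymph"]] > sm$pei[["perilymph"]]))
    stop("invalid signal model: perilymph must be brighter on PPI than on PEI ",
         "(PPI - PEI must be positive in perilymph)")
  if (!(sm$ppi[["endolymph"]] < sm$pei[["endolymph"]]))
    stop("invalid signal model: endolymph must be darker on PPI than on PEI ",
         "(PPI - PEI must be negative in endolymph)")
  if (!(sm$mrc[["perilymph"]] > sm$mrc[["bone"]]) ||
      !(sm$mrc[["endolymph"]] > sm$mrc[["bone"]]))
    stop("invalid signal model: fluid must be brighter than bone on MRC")
  invisible(sm)
}

#' @export
print.eh_signal_model <- function(x, ...) {
  cat("MR signal model (arbitrary units)\n")
  m <- rbind(MRC = x$mrc, PPI = x$ppi, PEI = x$pei)
  print(m)
  invisible(x)
}

# Smallest absolute compartment difference on the subtraction contrasts;
# used to express noise levels relative to the available contrast.
min_signal_difference <- function(sm) {
  min(abs(sm$ppi[["perilymph"]] - sm$pei[["perilymph"]]),
      abs(sm$ppi[["endolymph"]] - sm$pei[["endolymph"]]))
}
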