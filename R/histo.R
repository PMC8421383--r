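count_px <- function(labels, codes) sum(labels %in% codes)

#' Cochlear EH ratio on a histology section
#'
#' Sums the scala-media (endolymphatic space) areas of the basal, middle and
#' apical turns and divides by the whole cochlear fluid area. Areas are
#' label pixel counts; the ratio is therefore exact on the label grid.
#'
#' @param section An [eh_section()] of site `"cochlea"`.
#' @return An [eh_measurement()] with method `"histo_area"`.
#' @export
histo_cochlea_ratio <- function(section) {
  stopifnot(inherits(section, "eh_section"))
  lb <- eh_labels()
  sm <- 0L
  total <- 0L
  for (tn in c("basal", "middle", "apical")) {
    tpix <- count_px(section$labels, turn_codes(tn))
    if (tpix == 0L)
      stop("missing turn label: no '", tn, "' turn pixels in section")
    sm <- sm + count_px(section$labels, lb[[paste0("scala_media_", tn)]])
    total <- total + tpix
  }
  eh_measurement(site = "cochlea", side = section$side,
                 numerator_pixels = sm, denominator_pixels = total,
                 method = "histo_area", ear_id = section$ear_id)
}

#' Vestibular EH ratios on a histology section
#'
#' Computes the saccular ratio (saccule area / vestibule area), the
#' utricular ratio, and the combined vestibular EH ratio
#' ((saccule + utricle) / vestibule). The vestibule area is the entire
#' vestibule label (organs plus vestibular perilymph); organ areas include
#' any pixels herniated beyond the vestibule boundary, as a traced organ
#' contour would. Combined equals saccular + utricular exactly whenever no
#' pixel is herniated (disjoint label counts over a shared denominator) and
#' by construction otherwise.
#'
#' @param section An [eh_section()] of site `"vestibule"`.
#' @return A list of three [eh_measurement()]s: `combined`, `saccular`,
#'   `utricular`.
#' @export
histo_vestibule_ratios <- function(section) {
  stopifnot(inherits(section, "eh_section"))
  lb <- eh_labels()
  vest <- count_px(section$labels, vestibule_codes())
  if (vest == 0L)
    stop("vestibule area is zero in section")
  sac <- count_px(section$labels, lb[["saccule"]])
  utr <- count_px(section$labels, lb[["utricle"]])
  mk <- function(site, num)
    eh_measurement(site = site, side = section$side, numerator_pixels = num,
                   denominator_pixels = vest, method = "histo_area",
                   ear_id = section$ear_id)
  list(combined = mk("vestibule", sac + utr),
       saccular = mk("saccule", sac),
       utricular = mk("utricle", utr))
}

#' Semicircular-canal duct ratio on a histology section
#'
#' The endolymphatic share of a canal cross-section: membranous-duct area
#' divided by the full canal cross-sectional area, at either the ampullary
#' or the non-ampullary region. This duct/cross-section orientation keeps
#' the ratio in `[0, 1]`.
#'
#' @param section An [eh_section()] of site `"canal"`.
#' @param canal,region Checked against the section's metadata when given.
#' @return An [eh_measurement()] with method `"histo_area"`.
#' @export
histo_canal_ratio <- function(section, canal = section$canal,
                              region = section$region) {
  stopifnot(inherits(section, "eh_section"))
  if (!identical(canal, section$canal) || !identical(region, section$region))
    stop("section is a ", section$canal, "/", section$region,
         " cross-section, not ", canal, "/", region)
  codes <- canal_codes(canal)
  duct <- count_px(section$labels, codes$duct)
  total <- duct + count_px(section$labels, codes$peri)
  if (total == 0L)
    stop("canal cross-sectional area is zero in section")
  eh_measurement(site = paste("canal", canal, region, sep = "_"),
                 side = section$side, numerator_pixels = duct,
                 denominator_pixels = total, method = "histo_area",
                 ear_id = section$ear_id)
}

#' Detect herniation of the otolithic organs into the lateral canal
#'
#' Flags an organ as herniated when its overlap with the canal-territory
#' mask (the lateral-canal lumen outside the vestibule boundary) reaches
#' `min_overlap_pixels`. Works on a 2D [eh_section()] or a 3D
#' [eh_label_volume()] carrying a territory mask.
#'
#' @param x An `eh_section` or `eh_label_volume`.
#' @param min_overlap_pixels Minimum organ/territory overlap that counts as
#'   herniation (default 1: any protrusion counts).
#' @return An object of class `herniation_call` with fields `ear_id`,
#'   `call` (`"none"`, `"saccular"`, `"utricular"`, `"both"`) and the per-organ
#'   overlap pixel counts.
#' @export
detect_herniation <- function(x, min_overlap_pixels = 1L) {
  lb <- eh_labels()
  if (inherits(x, "eh_section")) {
    labels <- x$labels; terr <- x$territory; ear_id <- x$ear_id
  } else if (inherits(x, "eh_label_volume")) {
    labels <- x$labels; terr <- x$territory; ear_id <- NA_character_
  } else stop("x must be an eh_section or eh_label_volume")
  sac <- sum(labels[terr] == lb[["saccule"]])
  utr <- sum(labels[terr] == lb[["utricle"]])
  s <- sac >= min_overlap_pixels
  u <- utr >= min_overlap_pixels
  call <- if (s && u) "both" else if (s) "saccular" else if (u) "utricular" else "none"
  structure(list(ear_id = ear_id, call = call,
                 overlap = c(saccule = sac, utricle = utr),
                 min_overlap_pixels = as.integer(min_overlap_pixels)),
            class = "herniation_call")
}

#' @export
print.herniation_call <- function(x, ...) {
  cat(sprintf("herniation call: %s (saccule %d px, utricle %d px in territory)\n",
              x$call, x$overlap[["saccule"]], x$overlap[["utricle"]]))
  invisible(x)
}

#' Summarize cohort measurements and herniation calls
#'
#' Grouped summary of EH measurements (n, mean, SD per side, site and
#' method; SD uses the n-1 convention and is `NA` for a single measurement)
#' and, if calls are supplied, herniation proportions with explicit
#' numerators and denominators.
#'
#' @param measurements A data.frame as from [measurements_table()] (columns
#'   `side`, `site`, `method`, `ratio`, ...).
#' @param calls Optional: a data.frame with columns `side` and `call`
#'   (values `none`/`saccular`/`utricular`/`both`), or a list of
#'   [detect_herniation()] calls plus a `side` attribute per element.
#' @return A list with `summary` (data.frame) and `herniation` (data.frame
#'   or `NULL`).
#' @examples
#' m <- data.frame(side = "affected", site = "cochlea", method = "histo_area",
#'                 ratio = c(0.3, 0.35))
#' summarize_cohort(m)$summary
#' @export
summarize_cohort <- function(measurements, calls = NULL) {
  stopifnot(is.data.frame(measurements), nrow(measurements) > 0)
  if (!all(measurements$side %in% c("affected", "unaffected", "control")))
    stop("unknown group label in measurements: ",
         paste(setdiff(unique(measurements$side),
                       c("affected", "unaffected", "control")), collapse = ", "))
  key <- interaction(measurements$side, measurements$site, measurements$method,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(measurements, key), function(d) {
    data.frame(side = d$side[1], site = d$site[1], method = d$method[1],
               n = nrow(d), mean = mean(d$ratio),
               sd = if (nrow(d) > 1) stats::sd(d$ratio) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  hern <- NULL
  if (!is.null(calls)) {
    if (!is.data.frame(calls))
      calls <- do.call(rbind, lapply(calls, function(cl)
        data.frame(side = attr(cl, "side") %||% "affected", call = cl$call,
                   stringsAsFactors = FALSE)))
    if (!all(calls$call %in% c("none", "saccular", "utricular", "both")))
      stop("unknown herniation call value")
    hern <- do.call(rbind, lapply(split(calls, calls$side), function(d) {
      n <- nrow(d)
      n_ext <- sum(d$call != "none")
      data.frame(side = d$side[1], n = n,
                 n_extension = n_ext, prop_extension = n_ext / n,
                 n_saccular = sum(d$call %in% c("saccular", "both")),
                 n_utricular = sum(d$call %in% c("utricular", "both")),
                 stringsAsFactors = FALSE)
    }))
    rownames(hern) <- NULL
  }
  list(summary = summ, herniation = hern)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
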