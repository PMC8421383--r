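#' Two-group comparison with normality-gated test choice
#'
#' The study-level comparison workflow: Shapiro-Wilk normality is assessed
#' in each group at `alpha_normality`; if both groups are compatible with
#' normality a two-sided Welch (unequal-variance) t-test is used, otherwise
#' a two-sided Mann-Whitney (Wilcoxon rank-sum) test. A group with zero
#' variance has no defined Shapiro-Wilk statistic and is treated as
#' non-normal, routing the comparison to the rank test.
#'
#' @param a,b Numeric vectors of ratios (each of length >= 3, finite).
#' @param alpha Significance level for the group difference.
#' @param alpha_normality Level for the per-group Shapiro-Wilk tests.
#' @param labels Character length-2 group labels.
#' @return An object of class `eh_comparison`: group summaries, normality
#'   p-values, `method_used` (`"t_test"` or `"mann_whitney"`), `statistic`,
#'   `p_value`, `significant`.
#' @examples
#' r <- compare_groups(rnorm(20, 0.3, 0.1), rnorm(20, 0.1, 0.05))
#' r$method_used
#' @export
compare_groups <- function(a, b, alpha = 0.05, alpha_normality = 0.05,
                           labels = c("a", "b")) {
  if (length(a) < 3 || length(b) < 3)
    stop("insufficient sample: each group needs n >= 3")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("group values must be finite")
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)  # degenerate: treated as non-normal
    stats::shapiro.test(x)$p.value
  }
  norm_p <- c(shapiro_p(a), shapiro_p(b))
  both_normal <- all(!is.na(norm_p)) && all(norm_p >= alpha_normality)
  if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    method <- "t_test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    method <- "mann_whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(labels = labels,
                 n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)),
                 sd = c(stats::sd(a), stats::sd(b)),
                 normality_p = norm_p,
                 alpha = alpha, alpha_normality = alpha_normality,
                 method_used = method, statistic = statistic,
                 p_value = p, significant = p < alpha),
            class = "eh_comparison")
}

#' @export
print.eh_comparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean %.3f, sd %.3f) vs %s (n=%d, mean %.3f, sd %.3f)\n",
              x$labels[1], x$n[1], x$mean[1], x$sd[1],
              x$labels[2], x$n[2], x$mean[2], x$sd[2]))
  cat(sprintf("  %s: statistic %.3f, p = %.4g (%ssignificant at %.2g)\n",
              x$method_used, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

comparison_row <- function(cmp, comparison) {
  data.frame(comparison = comparison,
             group_a = cmp$labels[1], group_b = cmp$labels[2],
             n_a = cmp$n[1], n_b = cmp$n[2],
             mean_a = cmp$mean[1], mean_b = cmp$mean[2],
             sd_a = cmp$sd[1], sd_b = cmp$sd[2],
             method = cmp$method_used, statistic = cmp$statistic,
             p_value = cmp$p_value, significant = cmp$significant,
             stringsAsFactors = FALSE)
}

#' Run the study's validation comparisons on a measurement table
#'
#' Assembles the two-group comparisons of the study from a long measurement
#' table: cochlear and vestibular EH ratios affected vs. control, histology
#' vs. MRI for cochlea and vestibule (affected ears), saccular vs. utricular
#' ratios, and each canal/region across available side pairs. Comparisons
#' whose groups are missing raise an error naming the comparison (or are
#' skipped when `skip_missing = TRUE`).
#'
#' @param measurements Data.frame with columns `side`, `site`, `method`,
#'   `ratio` (e.g. from [measurements_table()]).
#' @param alpha,alpha_normality Passed to [compare_groups()].
#' @param skip_missing Skip comparisons with a missing or undersized group
#'   instead of failing.
#' @return A data.frame with one row per comparison (groups, summaries,
#'   branch taken, statistic, p-value, significance flag).
#' @export
run_validation_suite <- function(measurements, alpha = 0.05,
                                 alpha_normality = 0.05, skip_missing = FALSE) {
  stopifnot(is.data.frame(measurements))
  grab <- function(site, side, method = NULL) {
    d <- measurements[measurements$site == site & measurements$side == side, ]
    if (!is.null(method)) d <- d[d$method == method, ]
    d$ratio
  }
  plan <- list(
    list(name = "cochlea_affected_vs_control",
         a = function() grab("cochlea", "affected", "histo_area"),
         b = function() grab("cochlea", "control", "histo_area"),
         labels = c("affected", "control")),
    list(name = "vestibule_affected_vs_control",
         a = function() grab("vestibule", "affected", "histo_area"),
         b = function() grab("vestibule", "control", "histo_area"),
         labels = c("affected", "control")),
    list(name = "cochlea_histo_vs_mri",
         a = function() grab("cochlea", "affected", "histo_area"),
         b = function() grab("cochlea", "affected", "mri_negative_pixel"),
         labels = c("histology", "mri")),
    list(name = "vestibule_histo_vs_mri",
         a = function() grab("vestibule", "affected", "histo_area"),
         b = function() grab("vestibule", "affected", "mri_negative_pixel"),
         labels = c("histology", "mri")),
    list(name = "saccule_vs_utricle",
         a = function() grab("saccule", "affected", "histo_area"),
         b = function() grab("utricle", "affected", "histo_area"),
         labels = c("saccule", "utricle"))
  )
  canal_sites <- grep("^canal_", unique(measurements$site), value = TRUE)
  side_pairs <- list(c("affected", "unaffected"), c("affected", "control"),
                     c("unaffected", "control"))
  for (cs in canal_sites) {
    for (sp in side_pairs) {
      if (all(sp %in% measurements$side[measurements$site == cs])) {
        local({
          cs <- cs; sp <- sp
          plan[[length(plan) + 1L]] <<- list(
            name = paste0(cs, "_", sp[1], "_vs_", sp[2]),
            a = function() grab(cs, sp[1]),
            b = function() grab(cs, sp[2]),
            labels = sp)
        })
      }
    }
  }

  rows <- list()
  for (p in plan) {
    a <- p$a(); b <- p$b()
    if (length(a) < 3 || length(b) < 3) {
      if (skip_missing) next
      stop("missing group for comparison '", p$name, "' (n = ",
           length(a), " vs ", length(b), ")")
    }
    rows[[length(rows) + 1L]] <-
      comparison_row(compare_groups(a, b, alpha, alpha_normality, p$labels),
                     p$name)
  }
  if (length(rows) == 0L) stop("no comparison could be run on this table")
  do.call(rbind, rows)
}
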