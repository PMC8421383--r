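test_that("identical samples yield no detectable difference", {
  set.seed(21)
  x <- rnorm(12, 0.4, 0.1)
  r <- compare_groups(x, x)
  expect_gte(r$p_value, 0.99)
  expect_false(r$significant)
})

test_that("undersized or non-finite groups are rejected", {
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient sample")
  expect_error(compare_groups(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("the normality gate picks the branch the data call for", {
  set.seed(22)
  a <- rnorm(40, 0.5, 0.1); b <- rnorm(40, 0.52, 0.1)
  r <- compare_groups(a, b)
  expect_true(all(r$normality_p >= 0.05))
  expect_identical(r$method_used, "t_test")

  skew <- rexp(50)^3  # decisively non-normal
  r2 <- compare_groups(skew, rnorm(40, 0.5, 0.1))
  expect_lt(r2$normality_p[1], 0.05)
  expect_identical(r2$method_used, "mann_whitney")

  # zero-variance group: Shapiro-Wilk undefined, rank test must be used
  r3 <- compare_groups(rep(0.4, 10), rnorm(10, 0.5, 0.05))
  expect_true(is.na(r3$normality_p[1]))
  expect_identical(r3$method_used, "mann_whitney")

  # significance flag is exactly p < alpha
  expect_identical(r$significant, r$p_value < r$alpha)
  expect_identical(r2$significant, r2$p_value < r2$alpha)
})

test_that("the rank branch is invariant to joint monotone transforms", {
  set.seed(23)
  a <- rexp(30)^2; b <- rexp(30)^2 * 1.5
  r1 <- compare_groups(a, b)
  r2 <- compare_groups(log(a + 1), log(b + 1))
  expect_identical(r1$method_used, "mann_whitney")
  expect_identical(r2$method_used, "mann_whitney")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("type-I error is calibrated at the nominal level", {
  set.seed(24)
  hits <- vapply(seq_len(1000), function(i)
    compare_groups(rnorm(20, 0.3, 0.1), rnorm(20, 0.3, 0.1))$significant,
    logical(1))
  expect_lte(mean(hits), 0.07)  # binomial slack around alpha = 0.05
})

test_that("a histology-vs-MRI-sized difference is far weaker than case-control", {
  # cochlear ratios: histology 0.314 (0.118, n=54), MRI 0.372 (0.164, n=72),
  # control 0.064 (0.022, n=17). The histology/MRI gap is ~0.5 pooled SD
  # (direct simulation puts p > 0.05 in roughly a third of replicates),
  # whereas affected vs control is >2 SD and always decisive.
  set.seed(25)
  p_hm <- numeric(100); p_ac <- numeric(100)
  for (i in 1:100) {
    mri <- rnorm(72, 0.372, 0.164); hist <- rnorm(54, 0.314, 0.118)
    ctl <- rnorm(17, 0.064, 0.022)
    p_hm[i] <- compare_groups(mri, hist)$p_value
    p_ac[i] <- compare_groups(hist, ctl)$p_value
  }
  expect_gt(mean(p_hm > 0.05), 0.2)
  expect_true(all(p_ac < 1e-6))
  expect_gt(median(p_hm), 1e3 * median(p_ac))
})

test_that("the validation suite assembles the planned comparisons", {
  set.seed(26)
  mk <- function(side, site, method, n, mean, sd)
    data.frame(side = side, site = site, method = method,
               ratio = rnorm(n, mean, sd))
  meas <- rbind(
    mk("affected", "cochlea", "histo_area", 54, 0.314, 0.118),
    mk("control", "cochlea", "histo_area", 17, 0.064, 0.022),
    mk("affected", "vestibule", "histo_area", 54, 0.757, 0.205),
    mk("control", "vestibule", "histo_area", 17, 0.289, 0.062),
    mk("affected", "cochlea", "mri_negative_pixel", 72, 0.372, 0.164),
    mk("affected", "vestibule", "mri_negative_pixel", 72, 0.533, 0.250),
    mk("affected", "saccule", "histo_area", 54, 0.513, 0.214),
    mk("affected", "utricle", "histo_area", 54, 0.242, 0.124),
    mk("affected", "canal_anterior_ampullary", "histo_area", 54, 0.565, 0.096),
    mk("unaffected", "canal_anterior_ampullary", "histo_area", 18, 0.515, 0.050))
  rep <- run_validation_suite(meas)
  expect_identical(nrow(rep), 6L)  # 5 fixed comparisons + 1 canal side pair
  expect_true(rep$significant[rep$comparison == "cochlea_affected_vs_control"])
  expect_true(rep$significant[rep$comparison == "saccule_vs_utricle"])
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))

  # a missing group is an error naming the comparison, unless skipped
  expect_error(run_validation_suite(meas[meas$side != "control", ]),
               "cochlea_affected_vs_control")
  rep2 <- run_validation_suite(meas[meas$side != "control", ],
                               skip_missing = TRUE)
  expect_false("cochlea_affected_vs_control" %in% rep2$comparison)
})
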