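lb <- eh_labels()

# hand-built sections for exact boundary cases
manual_section <- function(labels, territory = NULL, site = "cochlea") {
  structure(list(labels = labels,
                 territory = territory %||%
                   matrix(FALSE, nrow(labels), ncol(labels)),
                 pixel_size_mm = c(0.5, 0.5), site = site,
                 canal = if (site == "canal") "anterior" else NA_character_,
                 region = if (site == "canal") "ampullary" else NA_character_,
                 ear_id = "manual", side = "affected", herniation = "none",
                 outlines = list()),
            class = "eh_section")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cochlear ratio hits its exact boundary values", {
  all_sm <- matrix(c(rep(lb[["scala_media_basal"]], 10),
                     rep(lb[["scala_media_middle"]], 10),
                     rep(lb[["scala_media_apical"]], 10),
                     rep(0L, 6)), 6, 6)
  expect_equal(histo_cochlea_ratio(manual_section(all_sm))$ratio, 1.0)
  no_sm <- matrix(c(rep(lb[["peri_basal"]], 10), rep(lb[["peri_middle"]], 10),
                    rep(lb[["peri_apical"]], 10), rep(0L, 6)), 6, 6)
  expect_equal(histo_cochlea_ratio(manual_section(no_sm))$ratio, 0.0)
  missing_turn <- no_sm
  missing_turn[missing_turn == lb[["peri_middle"]]] <- 0L
  expect_error(histo_cochlea_ratio(manual_section(missing_turn)),
               "missing turn label.*middle")
})

test_that("cochlear ratio recovers the generative fraction on a phantom", {
  spec <- phantom_spec(grid_shape = c(128L, 128L, 10L), noise_sd = 0,
                       cochlea_true_fraction = 0.314)
  sec <- render_histo_section(spec, "cochlea")
  r <- histo_cochlea_ratio(sec)
  # tolerance from the polygon oracle: one boundary row of the scala media
  sm_mask <- matrix(sec$labels %in% c(lb[["scala_media_basal"]],
                                      lb[["scala_media_middle"]],
                                      lb[["scala_media_apical"]]),
                    nrow(sec$labels))
  tol <- boundary_pixels(sm_mask) / sum(sm_mask) * 0.5
  expect_lt(abs(r$ratio - 0.314), tol)
})

test_that("vestibular ratios are additive and recover published structure", {
  spec <- phantom_spec(grid_shape = c(128L, 128L, 10L), noise_sd = 0,
                       saccule_true_fraction = 0.513,
                       utricle_true_fraction = 0.242)
  vr <- histo_vestibule_ratios(render_histo_section(spec, "vestibule"))
  expect_identical(vr$combined$denominator_pixels, vr$saccular$denominator_pixels)
  expect_equal(vr$combined$ratio, vr$saccular$ratio + vr$utricular$ratio)
  expect_lt(abs(vr$combined$ratio - 0.755), 0.015)
  # additivity to machine precision on random phantoms, herniated included
  set.seed(31)
  for (i in 1:5) {
    sp <- small_spec(saccule_true_fraction = runif(1, 0.2, 0.6),
                     utricle_true_fraction = runif(1, 0.1, 0.3),
                     herniation = sample(c("none", "saccular", "both"), 1),
                     seed = i)
    vr <- histo_vestibule_ratios(render_histo_section(sp, "vestibule"))
    expect_equal(vr$combined$ratio, vr$saccular$ratio + vr$utricular$ratio,
                 tolerance = 1e-15)
  }
})

test_that("vestibular ratios handle absent organs and empty vestibule", {
  v_only <- matrix(lb[["vestibule_peri"]], 4, 4)
  vr <- histo_vestibule_ratios(manual_section(v_only, site = "vestibule"))
  expect_equal(vr$combined$ratio, 0)
  expect_equal(vr$saccular$ratio, 0)
  expect_equal(vr$utricular$ratio, 0)
  expect_error(histo_vestibule_ratios(manual_section(matrix(0L, 4, 4),
                                                     site = "vestibule")),
               "vestibule area is zero")
})

test_that("canal duct ratios span their range and recover the phantom fraction", {
  full <- matrix(lb[["canal_duct_anterior"]], 4, 4)
  expect_equal(histo_canal_ratio(manual_section(full, site = "canal"))$ratio, 1.0)
  none <- matrix(lb[["canal_peri_anterior"]], 4, 4)
  expect_equal(histo_canal_ratio(manual_section(none, site = "canal"))$ratio, 0.0)
  expect_error(histo_canal_ratio(manual_section(matrix(0L, 4, 4), site = "canal")),
               "zero")

  spec <- phantom_spec(grid_shape = c(128L, 128L, 10L), noise_sd = 0,
                       canal_duct_fraction_ampullary =
                         c(anterior = 0.565, lateral = 0.511, posterior = 0.518))
  sec <- render_histo_section(spec, "canal", "anterior", "ampullary")
  expect_lt(abs(histo_canal_ratio(sec)$ratio - 0.565), 0.01)
  expect_error(histo_canal_ratio(sec, canal = "lateral"), "cross-section")
})

test_that("herniation calls round-trip the generator flag", {
  for (h in c("none", "saccular", "utricular", "both")) {
    sec <- render_histo_section(small_spec(herniation = h), "vestibule")
    expect_identical(detect_herniation(sec)$call, h)
  }
  # 3D labels: same round trip through the MR phantom
  ph <- render_mr_phantom(small_spec(herniation = "utricular"))
  expect_identical(detect_herniation(ph$labels)$call, "utricular")
})

test_that("herniation detection is translation invariant", {
  sec <- render_histo_section(small_spec(herniation = "saccular"), "vestibule")
  shift <- function(m, dx, dy, fill = FALSE) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[(1 + dx):nrow(m), (1 + dy):ncol(m)] <-
      m[1:(nrow(m) - dx), 1:(ncol(m) - dy)]
    out
  }
  moved <- manual_section(shift(sec$labels, 3, 5, 0L),
                          territory = shift(sec$territory, 3, 5),
                          site = "vestibule")
  expect_identical(detect_herniation(moved)$call,
                   detect_herniation(sec)$call)
  expect_identical(detect_herniation(moved)$overlap,
                   detect_herniation(sec)$overlap)
})

test_that("cohort summaries report exact group statistics", {
  m1 <- data.frame(side = "affected", site = "cochlea", method = "histo_area",
                   ratio = 0.42)
  s1 <- summarize_cohort(m1)$summary
  expect_equal(s1$mean, 0.42)
  expect_true(is.na(s1$sd))
  m2 <- rbind(data.frame(side = "affected", site = "cochlea",
                         method = "histo_area", ratio = rep(0.3, 4)),
              data.frame(side = "control", site = "cochlea",
                         method = "histo_area", ratio = rep(0.1, 5)))
  s2 <- summarize_cohort(m2)$summary
  expect_equal(sort(s2$mean), c(0.1, 0.3))
  expect_equal(s2$sd, c(0, 0))
  bad <- data.frame(side = "lesion", site = "cochlea", method = "histo_area",
                    ratio = 0.3)
  expect_error(summarize_cohort(bad), "unknown group label")
})

test_that("published herniation proportions follow from the printed counts", {
  histo_calls <- data.frame(
    side = "affected",
    call = rep(c("saccular", "utricular", "none"), c(15, 9, 30)))
  h <- summarize_cohort(
    data.frame(side = "affected", site = "vestibule", method = "histo_area",
               ratio = 0.5),
    calls = histo_calls)$herniation
  expect_identical(h$n_extension, 24L)
  expect_identical(h$n, 54L)
  expect_equal(round(100 * h$prop_extension, 1), 44.4)
  expect_identical(h$n_saccular, 15L)
  expect_identical(h$n_utricular, 9L)

  mri_calls <- data.frame(
    side = "affected",
    call = rep(c("saccular", "none"), c(29, 43)))
  h2 <- summarize_cohort(
    data.frame(side = "affected", site = "vestibule",
               method = "mri_negative_pixel", ratio = 0.5),
    calls = mri_calls)$herniation
  expect_identical(h2$n_extension, 29L)
  expect_equal(round(100 * h2$prop_extension, 1), 40.3)
})
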