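test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(saccule_true_fraction = 0.6,
                            utricle_true_fraction = 0.5),
               "sum.*< 1|must be < 1")
  expect_error(phantom_spec(cochlea_true_fraction = 0), "\\(0, 1\\)")
  expect_error(phantom_spec(cochlea_true_fraction = 1), "\\(0, 1\\)")
  expect_error(phantom_spec(noise_sd = -1), "nonnegative")
  expect_error(phantom_spec(grid_shape = c(32L, 128L, 10L)), "grid too small")
  expect_error(phantom_spec(grid_shape = c(128L, 128L, 4L)), "slices")
})

test_that("an inverted signal model is rejected", {
  expect_error(signal_model(ppi = c(bone = 0, perilymph = 100, endolymph = 500),
                            pei = c(bone = 0, perilymph = 500, endolymph = 100)),
               "perilymph")
  expect_error(signal_model(mrc = c(bone = 900, perilymph = 800, endolymph = 800)),
               "brighter than bone")
})

test_that("rendering is deterministic given the seed", {
  spec <- small_spec(noise_sd = 25, seed = 7L)
  a <- render_mr_phantom(spec)
  b <- render_mr_phantom(spec)
  expect_identical(a$ppi$data, b$ppi$data)
  expect_identical(a$mrc$data, b$mrc$data)
  expect_identical(a$labels$labels, b$labels$labels)
  s1 <- render_histo_section(spec, "vestibule")
  s2 <- render_histo_section(spec, "vestibule")
  expect_identical(s1$labels, s2$labels)
})

test_that("noiseless subtraction signs follow the compartments voxel-wise", {
  ph <- render_mr_phantom(small_spec())
  d <- ph$ppi$data - ph$pei$data
  endo <- ph$labels$labels %in% ehquant:::endolymph_codes()
  peri <- ph$labels$labels %in% ehquant:::perilymph_codes()
  bg <- ph$labels$labels %in% ehquant:::bone_codes()
  expect_true(all(d[endo] < 0))
  expect_true(all(d[peri] > 0))
  expect_true(all(d[bg] == 0))
})

test_that("vestibular areas are conserved and realize the spec fractions", {
  spec <- small_spec(saccule_true_fraction = 0.5, utricle_true_fraction = 0.25)
  ph <- render_mr_phantom(spec)
  sel <- select_vestibule_slice(ph$labels)
  pl <- ph$labels$labels[, , sel$slice]
  lb <- eh_labels()
  sac <- sum(pl == lb[["saccule"]])
  utr <- sum(pl == lb[["utricle"]])
  vperi <- sum(pl == lb[["vestibule_peri"]])
  vest <- sum(pl %in% ehquant:::vestibule_codes())
  # exact partition of the vestibule disk on the label grid
  expect_identical(sac + utr + vperi, vest)
  # realized endolymph fraction matches the spec within a boundary-row bound
  organ_mask <- matrix(pl %in% c(lb[["saccule"]], lb[["utricle"]]), nrow(pl))
  tol <- boundary_pixels(organ_mask) / (sac + utr)
  expect_lt(abs((sac + utr) / vest - 0.75), tol)
})

test_that("rendered fractions track the spec across random specs (round trip)", {
  set.seed(404)
  for (i in 1:8) {
    fs <- runif(1, 0.2, 0.7); fu <- runif(1, 0.05, min(0.25, 0.95 - fs))
    fc <- runif(1, 0.05, 0.8)
    spec <- phantom_spec(grid_shape = c(128L, 128L, 10L), noise_sd = 0,
                         cochlea_true_fraction = fc,
                         saccule_true_fraction = fs,
                         utricle_true_fraction = fu, seed = i)
    vr <- histo_vestibule_ratios(render_histo_section(spec, "vestibule"))
    cr <- histo_cochlea_ratio(render_histo_section(spec, "cochlea"))
    expect_lt(abs(vr$saccular$ratio - fs), 0.015)
    expect_lt(abs(vr$utricular$ratio - fu), 0.015)
    expect_lt(abs(cr$ratio - fc), 0.015)
  }
})

test_that("rasterized areas agree with the polygon (shoelace) oracle", {
  spec <- small_spec(grid_shape = c(128L, 128L, 10L),
                     cochlea_true_fraction = 0.314,
                     saccule_true_fraction = 0.513,
                     utricle_true_fraction = 0.242,
                     herniation = "saccular")
  lb <- eh_labels()

  sec <- render_histo_section(spec, "vestibule")
  for (region in c("saccule", "utricle", "vestibule")) {
    codes <- switch(region,
                    vestibule = ehquant:::vestibule_codes(),
                    lb[[region]])
    mask <- matrix(sec$labels %in% codes, nrow(sec$labels))
    expect_lt(abs(sum(mask) - poly_area(sec$outlines[[region]])),
              1.2 * boundary_pixels(mask) + 4)
  }

  secc <- render_histo_section(spec, "cochlea")
  for (tn in c("basal", "middle", "apical")) {
    nm <- paste0("scala_media_", tn)
    mask <- matrix(secc$labels == lb[[nm]], nrow(secc$labels))
    expect_lt(abs(sum(mask) - poly_area(secc$outlines[[nm]])),
              1.2 * boundary_pixels(mask) + 4)
  }

  seck <- render_histo_section(spec, "canal", "posterior", "nonampullary")
  mask <- matrix(seck$labels == lb[["canal_duct_posterior"]], nrow(seck$labels))
  expect_lt(abs(sum(mask) - poly_area(seck$outlines$duct)),
            1.2 * boundary_pixels(mask) + 4)
})

test_that("herniation flags render as organ pixels inside the canal territory", {
  lb <- eh_labels()
  organ_in_territory <- function(h) {
    sec <- render_histo_section(small_spec(herniation = h), "vestibule")
    c(saccule = sum(sec$labels[sec$territory] == lb[["saccule"]]),
      utricle = sum(sec$labels[sec$territory] == lb[["utricle"]]))
  }
  expect_identical(unname(organ_in_territory("none")), c(0L, 0L))
  ov <- organ_in_territory("saccular")
  expect_gt(ov[["saccule"]], 0); expect_identical(ov[["utricle"]], 0L)
  ov <- organ_in_territory("utricular")
  expect_identical(ov[["saccule"]], 0L); expect_gt(ov[["utricle"]], 0)
  ov <- organ_in_territory("both")
  expect_gt(ov[["saccule"]], 0); expect_gt(ov[["utricle"]], 0)
})
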