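test_that("extrapolation factors: forced ratio and whole-body identity", {
  e <- list(whole = c(muscle = 1000, subcutaneous_fat = 800,
                      visceral_fat = 300),
            cropped = c(muscle = 500, subcutaneous_fat = 400,
                        visceral_fat = 300))
  k <- build_extrapolation_factors(list(e), "abdomen_pelvis")
  expect_equal(unname(k$k[["muscle"]]), 2.0)
  expect_equal(unname(k$k[["subcutaneous_fat"]]), 2.0)
  expect_equal(unname(k$k[["visceral_fat"]]), 1.0)
  kw <- build_extrapolation_factors(field = "whole_body")
  expect_identical(unname(kw$k), c(1, 1, 1))
})

test_that("atlas factors equal the hand-computed mean of ratios", {
  set.seed(42)
  atlas <- lapply(1:5, function(i) {
    whole <- c(muscle = 1000 + 50 * i, subcutaneous_fat = 900 - 30 * i,
               visceral_fat = 200 + 10 * i)
    frac <- runif(3, 0.3, 0.8)
    list(whole = whole,
         cropped = round(whole * setNames(frac, names(whole))))
  })
  k <- build_extrapolation_factors(atlas, "abdomen_pelvis")
  for (t in c("muscle", "subcutaneous_fat", "visceral_fat")) {
    manual <- mean(vapply(atlas, function(e) e$whole[[t]] / e$cropped[[t]],
                          numeric(1)))
    expect_equal(unname(k$k[[t]]), manual)
  }
  expect_equal(k$atlas_size, 5L)
})

test_that("atlas factors from phantom tallies match per-entry arithmetic", {
  base <- coarse_spec()
  entries <- lapply(1:3, function(i) {
    ph <- generate_phantom(sample_phantom_spec(100L + i, base))
    cr <- crop_field(ph$volume, ph$truth, "abdomen_pelvis")
    atlas_entry(ph$truth, cr$truth)
  })
  k <- build_extrapolation_factors(entries, "abdomen_pelvis")
  manual <- rowMeans(vapply(entries, function(e)
    e$whole / e$cropped, numeric(3)))
  expect_equal(unname(k$k), unname(manual))
  expect_true(all(k$k >= 1))
})

test_that("zero cropped counts and invalid factors are rejected", {
  e <- list(whole = c(muscle = 10, subcutaneous_fat = 10, visceral_fat = 10),
            cropped = c(muscle = 0, subcutaneous_fat = 5, visceral_fat = 5))
  expect_error(build_extrapolation_factors(list(e), "abdomen_pelvis"),
               "entry 1")
  expect_error(build_extrapolation_factors(list(), "abdomen_pelvis"),
               "at least one")
  expect_error(extrapolation_factors(0.5, 1, 1, "abdomen_pelvis"), ">= 1")
  expect_error(extrapolation_factors(2, 1, 1, "whole_body"), "whole-body")
})

test_that("mass model applies densities, factors and height normalization", {
  kw <- build_extrapolation_factors(field = "whole_body")
  cst <- mass_constants(c(10, 10, 10))  # 1 mL voxels
  counts <- c(muscle = 2500, subcutaneous_fat = 1200, visceral_fat = 400)
  m <- compute_masses(counts, kw, cst, height_m = 1.7)
  expect_equal(unname(m$raw_kg[["MBM3D"]]), 2500 * 1.06 / 1000)
  expect_equal(unname(m$raw_kg[["SFM3D"]]), 1200 * 0.923 / 1000)
  expect_equal(unname(m$raw_kg[["VFM3D"]]), 400 * 0.923 / 1000)
  expect_equal(unname(m$normalized), unname(m$raw_kg) / 1.7^2)
  # extrapolation factor scales the tally linearly
  k2 <- extrapolation_factors(2, 3, 4, "abdomen_pelvis", 1L)
  m2 <- compute_masses(counts, k2, cst, height_m = 1.7)
  expect_equal(unname(m2$raw_kg[["MBM3D"]]), 2 * unname(m$raw_kg[["MBM3D"]]))
  expect_equal(unname(m2$raw_kg[["SFM3D"]]), 3 * unname(m$raw_kg[["SFM3D"]]))
  expect_equal(unname(m2$raw_kg[["VFM3D"]]), 4 * unname(m$raw_kg[["VFM3D"]]))
})

test_that("degenerate and scaling laws of the mass model", {
  kw <- build_extrapolation_factors(field = "whole_body")
  cst <- mass_constants(c(2, 2, 4))
  zero <- compute_masses(c(muscle = 0, subcutaneous_fat = 0,
                           visceral_fat = 0), kw, cst, 1.8)
  expect_true(all(zero$raw_kg == 0) && all(zero$normalized == 0))
  counts <- c(muscle = 987, subcutaneous_fat = 654, visceral_fat = 321)
  m1 <- compute_masses(counts, kw, cst, 1.6)
  m2 <- compute_masses(counts, kw, cst, 3.2)  # doubled height
  expect_equal(m1$raw_kg, m2$raw_kg)
  expect_equal(unname(m2$normalized), unname(m1$normalized) / 4)
  # spacing scaled by s multiplies every raw mass by s^3
  s <- 1.5
  m3 <- compute_masses(counts, kw, mass_constants(c(2, 2, 4) * s), 1.6)
  expect_equal(unname(m3$raw_kg), unname(m1$raw_kg) * s^3)
  expect_error(compute_masses(counts, kw, cst, -1), "height")
})

test_that("total fat mass is the sum of its compartments to machine precision", {
  kw <- build_extrapolation_factors(field = "whole_body")
  set.seed(99)
  for (i in 1:25) {
    counts <- c(muscle = sample(1e6, 1), subcutaneous_fat = sample(1e6, 1),
                visceral_fat = sample(1e6, 1))
    cst <- mass_constants(runif(3, 0.5, 5))
    h <- runif(1, 1.4, 2.1)
    m <- compute_masses(counts, kw, cst, h)
    expect_identical(unname(m$raw_kg[["FBM3D"]]),
                     unname(m$raw_kg[["VFM3D"]] + m$raw_kg[["SFM3D"]]))
    expect_equal(unname(m$normalized[["FBM3D"]]),
                 unname(m$normalized[["VFM3D"]] + m$normalized[["SFM3D"]]),
                 tolerance = 1e-12)
  }
})

test_that("L3 areas: empty slice, exact additivity, annulus oracle", {
  dm <- c(6, 6, 4)
  empty <- tissue_masks(array(FALSE, dm), array(FALSE, dm), array(FALSE, dm))
  ar <- compute_l3_areas(empty, 2L, c(2, 2, 4), 1.7)
  expect_true(all(ar$raw_cm2 == 0))
  expect_error(compute_l3_areas(empty, 9L, c(2, 2, 4), 1.7), "axial range")

  ph <- default_phantom()
  masks <- default_segmentation()
  spec <- coarse_spec()
  l3 <- locate_L3(ph$volume, ph$truth)
  ar2 <- compute_l3_areas(masks, l3, ph$volume$spacing, spec$height_m)
  expect_equal(unname(ar2$raw_cm2[["FBA2D"]]),
               unname(ar2$raw_cm2[["VFA2D"]] + ar2$raw_cm2[["SFA2D"]]))
  analytic <- analytic_l3_muscle_area_mm2(spec) / 100  # cm2
  expect_lt(abs(ar2$raw_cm2[["MBA2D"]] / analytic - 1), 0.05)
})

test_that("atlas of the phantom itself reproduces whole-body masses exactly", {
  ph <- default_phantom()
  cr <- crop_field(ph$volume, ph$truth, "abdomen_pelvis")
  k <- build_extrapolation_factors(list(atlas_entry(ph$truth, cr$truth)),
                                   "abdomen_pelvis")
  cst <- mass_constants(ph$volume$spacing)
  h <- ph$volume$height_m
  whole <- compute_masses(ph$truth,
                          build_extrapolation_factors(field = "whole_body"),
                          cst, h)
  back <- compute_masses(cr$truth, k, cst, h)
  expect_equal(back$raw_kg, whole$raw_kg)
})

test_that("anthro_result assembles the eight parameters", {
  kw <- build_extrapolation_factors(field = "whole_body")
  cst <- mass_constants(c(2, 2, 4))
  m <- compute_masses(c(muscle = 100, subcutaneous_fat = 50,
                        visceral_fat = 20), kw, cst, 1.7)
  dm <- c(4, 4, 2)
  tm <- tissue_masks(array(TRUE, dm) & rep(c(TRUE, FALSE), 16),
                     array(FALSE, dm), array(FALSE, dm))
  a <- compute_l3_areas(tm, 1L, c(2, 2, 4), 1.7)
  res <- anthro_result(m, a)
  expect_true(all(anthro_parameters() %in% names(res)))
  expect_equal(res$FBM3D, res$VFM3D + res$SFM3D)
})
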