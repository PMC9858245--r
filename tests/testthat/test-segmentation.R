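test_that("an all-air volume raises an empty-body error", {
  v <- ct_volume(array(-1000, c(8, 8, 4)), c(2, 2, 2))
  expect_error(extract_body_mask(v), "empty body")
})

test_that("body mask matches the phantom body and is one component", {
  ph <- default_phantom()
  body <- extract_body_mask(ph$volume)
  truth_body <- sum(ph$truth$counts) - ph$truth$counts[["background"]]
  expect_lt(abs(sum(body) / truth_body - 1), 0.01)
  labs <- ctanthro:::label_components_3d(body)
  expect_equal(max(labs), 1L)
})

test_that("tissue masks are disjoint, body-contained and near ground truth", {
  ph <- default_phantom()
  masks <- default_segmentation()
  body <- extract_body_mask(ph$volume)
  expect_false(any(masks$muscle & masks$subcutaneous_fat))
  expect_false(any(masks$muscle & masks$visceral_fat))
  expect_false(any(masks$subcutaneous_fat & masks$visceral_fat))
  expect_true(all(body[masks$muscle]))
  expect_true(all(body[masks$subcutaneous_fat]))
  expect_true(all(body[masks$visceral_fat]))
  gt <- ph$truth$counts
  expect_lt(abs(masks$counts[["muscle"]] / gt[["muscle"]] - 1), 0.05)
  expect_lt(abs(masks$counts[["subcutaneous_fat"]] /
                  gt[["subcutaneous_fat"]] - 1), 0.05)
  expect_lt(abs(masks$counts[["visceral_fat"]] /
                  gt[["visceral_fat"]] - 1), 0.05)
})

test_that("muscle-wall restriction excludes organ sharing the muscle window", {
  hp <- default_hu_params()
  hp$mean[hp$class == "organ"] <- 40  # organ indistinguishable from muscle by HU
  ph <- generate_phantom(coarse_spec(seed = 21L, hu_params = hp))
  masks <- suppressWarnings(segment_volume(ph$volume))
  expect_gte(dice_coef(masks$muscle, ph$truth$labels == GT_LABELS[["muscle"]]),
             0.90)
})

test_that("fat split partitions the fat mask exactly", {
  ph <- default_phantom()
  body <- extract_body_mask(ph$volume)
  cls <- classify_tissues(ph$volume, body)
  masks <- suppressWarnings(
    split_fat(cls$fat, cls$muscle, body, spacing = ph$volume$spacing))
  expect_equal(masks$counts[["subcutaneous_fat"]] +
                 masks$counts[["visceral_fat"]], sum(cls$fat))
  expect_true(all(cls$fat == (masks$subcutaneous_fat | masks$visceral_fat)))
})

test_that("a volume without fat-window voxels yields an empty fat mask", {
  # muscle-HU disc in air: a body with no adipose tissue
  vox <- array(-1000, c(24, 24, 3))
  xy <- expand.grid(x = 1:24, y = 1:24)
  disc <- (xy$x - 12)^2 + (xy$y - 12)^2 <= 64
  for (k in 1:3) vox[, , k][disc] <- 40
  v <- ct_volume(vox, c(4, 4, 6))
  body <- extract_body_mask(v)
  cls <- classify_tissues(v, body, segmentation_params(min_component_voxels = 1L))
  expect_equal(sum(cls$fat), 0)
  expect_gt(sum(cls$muscle), 0)
})

test_that("components below the size floor are discarded as noise", {
  ph <- generate_phantom(tiny_spec(seed = 31L))
  vox <- ph$volume$voxels
  ref <- suppressWarnings(segment_volume(ph$volume))
  # implant a tiny fat speck inside the thoracic organ compartment
  lm <- ph$volume$landmarks
  k <- lm$diaphragm + 3L
  ctr <- round(dim(vox)[1:2] / 2)
  vox[ctr[1] + (0:1), ctr[2] + (0:1), k] <- -100
  v2 <- ct_volume(vox, ph$volume$spacing, "whole_body",
                  ph$volume$height_m, ph$volume$landmarks)
  withspeck <- suppressWarnings(segment_volume(v2))
  # the 8-voxel speck is below the 64-voxel floor: no fat is added
  expect_identical(withspeck$counts[["subcutaneous_fat"]] +
                     withspeck$counts[["visceral_fat"]],
                   ref$counts[["subcutaneous_fat"]] +
                     ref$counts[["visceral_fat"]])
  expect_false(any(withspeck$visceral_fat[ctr[1] + (0:1), ctr[2] + (0:1), k] |
                     withspeck$subcutaneous_fat[ctr[1] + (0:1),
                                                ctr[2] + (0:1), k]))
})

test_that("thickening the true subcutaneous ring increases the measured count", {
  thin <- suppressWarnings(
    segment_volume(generate_phantom(tiny_spec(subcutaneous_thickness = 16))$volume))
  thick <- suppressWarnings(
    segment_volume(generate_phantom(tiny_spec(subcutaneous_thickness = 24))$volume))
  expect_gt(thick$counts[["subcutaneous_fat"]],
            thin$counts[["subcutaneous_fat"]])
})

test_that("segmentation is deterministic", {
  ph <- generate_phantom(tiny_spec(seed = 41L))
  a <- suppressWarnings(segment_volume(ph$volume))
  b <- suppressWarnings(segment_volume(ph$volume))
  expect_identical(a$counts, b$counts)
  expect_identical(a$muscle, b$muscle)
})

test_that("L3 location: landmark passthrough and crop offset agree", {
  ph <- default_phantom()
  expect_identical(locate_L3(ph$volume), ph$truth$L3_slice_index)
  cr <- crop_field(ph$volume, ph$truth, "abdomen_pelvis")
  lm <- ph$volume$landmarks
  expect_identical(locate_L3(cr$volume, cr$truth),
                   ph$truth$L3_slice_index - lm$ischium + 1L)
})

test_that("bone-profile heuristic finds L3 near the landmark", {
  ph <- default_phantom()
  v <- ph$volume
  v$landmarks <- NULL
  est <- locate_L3(v)
  dz <- v$spacing[3]
  expect_lt(abs(est - ph$truth$L3_slice_index) * dz, 25)  # within 25 mm
  # and on the cropped field
  cr <- crop_field(ph$volume, ph$truth, "abdomen_pelvis")
  v2 <- cr$volume
  v2$landmarks <- NULL
  expect_lt(abs(locate_L3(v2) - cr$truth$L3_slice_index) * dz, 25)
})

test_that("fields without an abdominal region are refused", {
  ph <- default_phantom()
  lm <- ph$volume$landmarks
  thorax_only <- crop_slices(ph$volume, ph$truth,
                             lm$diaphragm + 2L, lm$shoulder)
  v <- thorax_only$volume
  v$landmarks <- NULL
  expect_error(locate_L3(v), "abdominal|contrast")
  boneless <- ct_volume(array(0, c(6, 6, 6)), c(2, 2, 2))
  expect_error(locate_L3(boneless), "bone")
})

test_that("segmentation parameter validation", {
  expect_error(segmentation_params(fat_hu_window = c(-30, -190)), "non-empty")
  expect_error(segmentation_params(fat_hu_window = c(-190, 0),
                                   muscle_hu_window = c(-29, 150)),
               "overlap")
  expect_error(segmentation_params(closing_radius_mm = -1), "radius")
})
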