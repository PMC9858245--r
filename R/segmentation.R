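# Rule-based tissue segmentation: HU windowing plus a slice-wise
# morphological muscle-wall rule that separates visceral from subcutaneous
# fat and excludes organ tissue sharing the muscle window.

#' Segmentation parameters
#'
#' @param fat_hu_window Hounsfield window for adipose tissue, default the
#'   literature-standard `[-190, -30]`.
#' @param muscle_hu_window Hounsfield window for skeletal muscle, default
#'   `[-29, +150]`. Must not overlap the fat window.
#' @param body_threshold HU threshold separating the body from surrounding
#'   air; lung parenchyma falls below it and is recovered by slice-wise
#'   hole filling.
#' @param closing_radius_mm Radius of the slice-wise morphological closing
#'   that turns the segmented muscle into a quasi-continuous wall.
#' @param min_component_voxels Connected components (3D) smaller than this
#'   are discarded as noise.
#' @param bone_hu_threshold HU above which voxels are treated as bone for
#'   wall completion and for the L3 bone-profile heuristic.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(fat_hu_window = c(-190, -30),
                                muscle_hu_window = c(-29, 150),
                                body_threshold = -500,
                                closing_radius_mm = 8,
                                min_component_voxels = 64L,
                                bone_hu_threshold = 200) {
  stopifnot(length(fat_hu_window) == 2L, length(muscle_hu_window) == 2L)
  if (diff(fat_hu_window) <= 0 || diff(muscle_hu_window) <= 0) {
    stop("HU windows must be non-empty [lo, hi] intervals", call. = FALSE)
  }
  if (max(fat_hu_window[1], muscle_hu_window[1]) <=
      min(fat_hu_window[2], muscle_hu_window[2])) {
    stop("fat and muscle HU windows must not overlap", call. = FALSE)
  }
  if (closing_radius_mm < 0) stop("closing radius must be >= 0", call. = FALSE)
  structure(list(fat_hu_window = fat_hu_window,
                 muscle_hu_window = muscle_hu_window,
                 body_threshold = body_threshold,
                 closing_radius_mm = closing_radius_mm,
                 min_component_voxels = as.integer(min_component_voxels),
                 bone_hu_threshold = bone_hu_threshold),
            class = "segmentation_params")
}

closing_brush <- function(volume, params) {
  px <- mean(volume$spacing[1:2])
  disc_brush(max(1L, round(params$closing_radius_mm / px)))
}

#' Extract the body mask
#'
#' Thresholds the volume at `body_threshold`, keeps the largest 3D
#' connected component (discarding disconnected clutter) and fills internal
#' holes slice-wise so low-attenuation interior structures (lung) stay
#' inside the body.
#'
#' @param volume A `ct_volume`.
#' @param params A [segmentation_params()].
#' @return Logical 3D array.
#' @export
extract_body_mask <- function(volume, params = segmentation_params()) {
  m <- volume$voxels > params$body_threshold
  if (!any(m)) stop("empty body: no voxel above body_threshold", call. = FALSE)
  fill_slices(largest_component_3d(m))
}

#' Classify fat and muscle voxels
#'
#' Fat is all body tissue inside the fat HU window. Muscle is body tissue
#' inside the muscle HU window restricted to the morphological muscle-wall
#' shell: per axial slice, wall-forming components (muscle components in
#' contact with the boundary-adjacent subcutaneous fat or with the body
#' boundary itself, completed by adjacent bone such as the skull) are
#' closed, and candidate components lying mostly inside the enclosed cavity
#' -- organ tissue sharing the muscle window -- are removed. Components
#' smaller than `min_component_voxels` are discarded from both masks.
#'
#' @param volume A `ct_volume`.
#' @param body_mask Logical array from [extract_body_mask()].
#' @param params A [segmentation_params()].
#' @return List with logical arrays `fat` and `muscle` (disjoint).
#' @export
classify_tissues <- function(volume, body_mask,
                             params = segmentation_params()) {
  hu <- volume$voxels
  fat <- body_mask & hu >= params$fat_hu_window[1] &
    hu <= params$fat_hu_window[2]
  raw_muscle <- body_mask & hu >= params$muscle_hu_window[1] &
    hu <= params$muscle_hu_window[2]
  bone <- body_mask & hu > params$bone_hu_threshold
  brush <- closing_brush(volume, params)
  adj <- disc_brush(1L)

  # Band just inside the body boundary; subcutaneous fat touches it.
  band <- body_mask & !erode_slices(body_mask, adj)
  fat_lab <- label_slices(fat)
  sub_ids <- setdiff(unique(fat_lab[band]), 0L)
  sub_cand <- array(fat_lab %in% sub_ids, dim(fat))
  seed <- dilate_slices(sub_cand, adj) | band

  # Wall = boundary-adjacent muscle components, completed by
  # boundary-adjacent bone (e.g. the skull).
  raw_lab <- label_slices(raw_muscle)
  wall_ids <- setdiff(unique(raw_lab[seed]), 0L)
  wall <- array(raw_lab %in% wall_ids, dim(fat))
  bone_lab <- label_slices(bone)
  bwall_ids <- setdiff(unique(bone_lab[seed]), 0L)
  wall <- wall | array(bone_lab %in% bwall_ids, dim(fat))

  closed <- close_slices(wall, brush)
  cavity <- fill_slices(closed) & !closed

  # Drop candidate components lying mostly inside the enclosed cavity
  # (organ tissue sharing the muscle window).
  muscle <- raw_muscle
  ids <- raw_lab[raw_lab > 0L]
  if (length(ids)) {
    tot <- tabulate(ids)
    inside <- tabulate(raw_lab[cavity & raw_lab > 0L], nbins = length(tot))
    drop_ids <- which(inside / tot > 0.5)
    if (length(drop_ids)) {
      muscle <- muscle & !array(raw_lab %in% drop_ids, dim(fat))
    }
  }
  fat <- remove_small_components_3d(fat, params$min_component_voxels)
  muscle <- remove_small_components_3d(muscle, params$min_component_voxels)
  list(fat = fat, muscle = muscle)
}

#' Split fat into subcutaneous and visceral compartments
#'
#' Per axial slice the muscle mask is morphologically closed into a
#' quasi-continuous wall; fat enclosed by the wall is visceral, all other
#' fat (outside the wall's outer contour, or on slices without any muscle
#' wall, for which a warning is issued) is subcutaneous. The two masks
#' partition the fat mask exactly.
#'
#' @param fat,muscle Logical arrays from [classify_tissues()].
#' @param body_mask Logical array from [extract_body_mask()].
#' @param params A [segmentation_params()].
#' @param spacing Voxel spacing (mm), used to size the closing element.
#' @return A [tissue_masks()] object.
#' @export
split_fat <- function(fat, muscle, body_mask, params = segmentation_params(),
                      spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(fat), dim(muscle)))
  px <- mean(spacing[1:2])
  brush <- disc_brush(max(1L, round(params$closing_radius_mm / px)))
  wall <- close_slices(muscle, brush)
  enclosed <- fill_slices(wall) & !wall
  visceral <- fat & enclosed
  # Slices carrying fat but no muscle wall keep all fat subcutaneous.
  n_no_wall <- sum(apply(fat, 3, any) & !apply(muscle, 3, any))
  if (n_no_wall > 0L) {
    warning(n_no_wall, " slice(s) without a muscle wall; their fat was ",
            "assigned to the subcutaneous compartment", call. = FALSE)
  }
  subcutaneous <- fat & !visceral
  tissue_masks(muscle = muscle, subcutaneous_fat = subcutaneous,
               visceral_fat = visceral)
}

#' Tissue mask container
#'
#' @param muscle,subcutaneous_fat,visceral_fat Congruent, pairwise-disjoint
#'   logical 3D arrays.
#' @return A `tissue_masks` object carrying the three masks and their voxel
#'   counts (`N_muscle`, `N_subcutaneous_fat`, `N_visceral_fat`).
#' @export
tissue_masks <- function(muscle, subcutaneous_fat, visceral_fat) {
  stopifnot(identical(dim(muscle), dim(subcutaneous_fat)),
            identical(dim(muscle), dim(visceral_fat)))
  if (any(muscle & subcutaneous_fat) || any(muscle & visceral_fat) ||
      any(subcutaneous_fat & visceral_fat)) {
    stop("tissue masks must be pairwise disjoint", call. = FALSE)
  }
  structure(list(muscle = muscle, subcutaneous_fat = subcutaneous_fat,
                 visceral_fat = visceral_fat,
                 counts = c(muscle = sum(muscle),
                            subcutaneous_fat = sum(subcutaneous_fat),
                            visceral_fat = sum(visceral_fat))),
            class = "tissue_masks")
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat("<tissue_masks> voxel counts:\n")
  print(x$counts)
  invisible(x)
}

#' Segment a CT volume into the three tissue compartments
#'
#' Convenience wrapper chaining [extract_body_mask()], [classify_tissues()]
#' and [split_fat()].
#'
#' @param volume A `ct_volume`.
#' @param params A [segmentation_params()].
#' @return A [tissue_masks()] object.
#' @export
segment_volume <- function(volume, params = segmentation_params()) {
  body <- extract_body_mask(volume, params)
  cls <- classify_tissues(volume, body, params)
  split_fat(cls$fat, cls$muscle, body, params, spacing = volume$spacing)
}

#' Locate the L3 vertebral level
#'
#' For phantoms the construction landmark is returned directly. Without
#' landmarks a bone-profile heuristic is used: per-slice bone area
#' (HU above `bone_hu_threshold`) exhibits a low plateau between the pelvic
#' bones below and the rib cage above; the L3 level is taken as the
#' midpoint of the longest such interior plateau. The heuristic refuses
#' fields without an identifiable abdominal region (for example a
#' thorax-only acquisition).
#'
#' @param volume A `ct_volume`.
#' @param truth Optional `ground_truth`; when supplied its recorded L3
#'   index is returned.
#' @param params A [segmentation_params()] (bone threshold).
#' @return Integer axial slice index (1-based).
#' @export
locate_L3 <- function(volume, truth = NULL, params = segmentation_params()) {
  if (!is.null(truth)) {
    idx <- truth$L3_slice_index
    if (is.na(idx)) stop("L3 level lies outside this volume", call. = FALSE)
    return(idx)
  }
  lm <- volume$landmarks
  if (!is.null(lm) && !is.null(lm$L3) && !is.na(lm$L3)) return(lm$L3)
  pixel_area <- prod(volume$spacing[1:2])
  bone_area <- apply(volume$voxels > params$bone_hu_threshold, 3, sum) *
    pixel_area
  if (all(bone_area == 0)) {
    stop("no bone found; cannot locate the L3 level", call. = FALSE)
  }
  rng <- range(bone_area)
  if (diff(rng) < 1000) {
    stop("bone profile lacks contrast; abdominal region not identifiable",
         call. = FALSE)
  }
  thr <- rng[1] + 0.35 * diff(rng)
  low <- bone_area < thr
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- length(low)
  dz <- volume$spacing[3]
  min_run <- ceiling(60 / dz)     # plateau must span >= 60 mm
  min_bracket <- ceiling(18 / dz) # flanked by >= 18 mm of high bone area
  cand <- which(r$values & r$lengths >= min_run &
                  starts > min_bracket & ends <= nz - min_bracket)
  if (!length(cand)) {
    stop("field lacks an identifiable abdominal region", call. = FALSE)
  }
  best <- cand[which.max(r$lengths[cand])]
  as.integer(round((starts[best] + ends[best]) / 2))
}
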