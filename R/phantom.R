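# Synthetic CT phantoms: stylized whole-body anatomy built from stacked
# elliptical cylinders with voxel-exact ground-truth tissue labels.

# Axial stations as fractions of body length, measured from the feet.
# Boundaries double as acquisition-field landmarks.
.station_fractions <- c(
  ischium   = 0.48,   # top of legs / bottom of pelvis
  iliac     = 0.585,  # top of pelvic bone / bottom of abdomen
  diaphragm = 0.72,   # top of abdomen / bottom of thorax
  shoulder  = 0.87,   # top of thorax / bottom of neck
  neck_top  = 0.905   # bottom of head
)

# Fixed internal anatomy constants (mm); not part of the user-facing spec.
.anat <- list(
  spine_r = 15, femur_r = 12, rib_thickness = 5, skull_thickness = 10,
  pelvic_bone = c(a = 35, b = 20), pelvic_bone_cx = 60, pelvic_bone_cy = -10,
  lung = c(a = 45, b = 50), lung_cx = 60, lung_cy = 5,
  field_margin_mm = 30  # abdomino-pelvic fields include the lung bases
)

# Internal tissue codes used while building a phantom.
.TC <- c(air = 0L, lung = 1L, organ = 2L, bone = 3L, muscle = 4L,
         fat_sub = 5L, fat_visc = 6L)

# Ground-truth label codes (exported contract).
#' Ground-truth label codes
#'
#' Integer codes used in ground-truth label volumes: 0 background, 1 muscle,
#' 2 subcutaneous fat, 3 visceral fat, 4 other tissue (organ, bone, lung).
#' @export
GT_LABELS <- c(background = 0L, muscle = 1L, subcutaneous_fat = 2L,
               visceral_fat = 3L, other_tissue = 4L)

#' Specify a synthetic CT phantom
#'
#' Defines the stylized whole-body anatomy used by [generate_phantom()]:
#' nested generalized cylinders (skin boundary, subcutaneous fat ring,
#' muscle wall, visceral cavity with organ tissue and visceral fat, plus
#' bone landmarks: femurs, pelvis, spine, ribs, skull).
#'
#' @param height_m Body height in metres; the phantom body length is
#'   `1000 * height_m` mm.
#' @param torso_radii Named list of in-plane semi-axes (mm): `legs_r`,
#'   `leg_offset`, `pelvis`, `abdomen`, `thorax` (each `c(a, b)` for the
#'   lateral/antero-posterior semi-axes), `neck_r`, `head`.
#' @param subcutaneous_thickness Uniform subcutaneous fat thickness, mm.
#' @param muscle_thickness Uniform muscle wall thickness, mm.
#' @param visceral_fat_fraction Fraction of the abdomino-pelvic visceral
#'   cavity occupied by visceral fat (the rest is organ tissue), in `[0, 1]`.
#' @param hu_params Data frame with columns `class`, `mean`, `sd`: Gaussian
#'   Hounsfield-unit parameters per tissue class
#'   (`air`, `lung`, `organ`, `bone`, `muscle`, `fat`).
#' @param spacing Voxel spacing `c(x, y, z)` in mm.
#' @param seed Integer seed controlling the HU noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height_m = 1.75,
                         torso_radii = list(
                           legs_r = 70, leg_offset = 75,
                           pelvis = c(160, 110), abdomen = c(150, 105),
                           thorax = c(155, 105), neck_r = 55,
                           head = c(80, 95)),
                         subcutaneous_thickness = 20,
                         muscle_thickness = 15,
                         visceral_fat_fraction = 0.35,
                         hu_params = default_hu_params(),
                         spacing = c(2, 2, 4),
                         seed = 1L) {
  spec <- structure(list(
    height_m = height_m, body_length = 1000 * height_m,
    torso_radii = torso_radii,
    subcutaneous_thickness = subcutaneous_thickness,
    muscle_thickness = muscle_thickness,
    visceral_fat_fraction = visceral_fat_fraction,
    hu_params = hu_params, spacing = spacing, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default Hounsfield-unit class parameters
#'
#' Means chosen so standard tissue windows separate the classes while organ
#' and muscle overlap (both fall in the muscle window), which is what makes
#' the morphological muscle-wall rule necessary.
#' @return Data frame with columns `class`, `mean`, `sd` (HU).
#' @export
default_hu_params <- function() {
  data.frame(
    class = c("air", "lung", "organ", "bone", "muscle", "fat"),
    mean  = c(-1000, -750, 55, 700, 40, -100),
    sd    = 15)
}

validate_phantom_spec <- function(spec) {
  tr <- spec$torso_radii
  stop_if_not_scalar_pos(spec$height_m, "height_m")
  if (!is.numeric(spec$spacing) || length(spec$spacing) != 3L ||
      any(spec$spacing <= 0)) {
    stop("`spacing` must be three positive mm values", call. = FALSE)
  }
  if (spec$visceral_fat_fraction < 0 || spec$visceral_fat_fraction > 1) {
    stop("`visceral_fat_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (spec$subcutaneous_thickness < 0) {
    stop("`subcutaneous_thickness` must be >= 0", call. = FALSE)
  }
  stop_if_not_scalar_pos(spec$muscle_thickness, "muscle_thickness")
  rr <- unlist(tr)
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("all torso radii must be positive", call. = FALSE)
  }
  ts <- spec$subcutaneous_thickness
  tm <- spec$muscle_thickness
  # Muscle wall must not self-intersect: every station needs a positive
  # interior after removing fat ring, muscle wall and embedded bone.
  checks <- c(
    legs   = tr$legs_r - ts - .anat$femur_r - 2,
    pelvis = min(tr$pelvis) - ts - tm - 5,
    abdomen = min(tr$abdomen) - ts - tm - 5,
    thorax = min(tr$thorax) - ts - tm - .anat$rib_thickness - 5,
    neck   = tr$neck_r - ts - .anat$spine_r - 2,
    head   = min(tr$head) - ts - .anat$skull_thickness - 5)
  bad <- names(checks)[checks <= 0]
  if (length(bad)) {
    stop("muscle wall self-intersects at station(s): ",
         paste(bad, collapse = ", "),
         " (radii too small for the configured thicknesses)", call. = FALSE)
  }
  invisible(spec)
}

#' Draw a randomized phantom specification
#'
#' Samples anatomy parameters around a base specification: height from a
#' normal population (SD 0.09 m), radii jittered by +/-5%, fat/muscle
#' thicknesses by +/-10%, and visceral fat fraction uniform on
#' `[0.25, 0.45]`. Used to build atlas populations and held-out phantoms
#' from one distribution.
#'
#' @param seed Integer seed (also stored in the returned spec).
#' @param base A `phantom_spec` providing the central anatomy.
#' @return A `phantom_spec`.
#' @export
sample_phantom_spec <- function(seed, base = phantom_spec()) {
  with_seed(seed, {
    jit <- function(x, f) x * runif(length(x), 1 - f, 1 + f)
    tr <- base$torso_radii
    tr$legs_r  <- jit(tr$legs_r, 0.05)
    tr$pelvis  <- jit(tr$pelvis, 0.05)
    tr$abdomen <- jit(tr$abdomen, 0.05)
    tr$thorax  <- jit(tr$thorax, 0.05)
    tr$neck_r  <- jit(tr$neck_r, 0.05)
    tr$head    <- jit(tr$head, 0.05)
    phantom_spec(
      height_m = max(1.45, min(2.05, rnorm(1, base$height_m, 0.09))),
      torso_radii = tr,
      subcutaneous_thickness = jit(base$subcutaneous_thickness, 0.10),
      muscle_thickness = jit(base$muscle_thickness, 0.10),
      visceral_fat_fraction = runif(1, 0.25, 0.45),
      hu_params = base$hu_params,
      spacing = base$spacing,
      seed = as.integer(seed))
  })
}

# Landmark z positions in mm from the feet.
landmarks_mm <- function(spec) {
  f <- .station_fractions
  L <- spec$body_length
  c(ischium = f[["ischium"]] * L, iliac = f[["iliac"]] * L,
    diaphragm = f[["diaphragm"]] * L, shoulder = f[["shoulder"]] * L,
    neck_top = f[["neck_top"]] * L,
    L3 = (f[["iliac"]] + f[["diaphragm"]]) / 2 * L)
}

#' Generate a synthetic whole-body CT phantom
#'
#' Builds the labelled anatomy defined by a [phantom_spec()] on a voxel grid
#' and draws Hounsfield units per tissue class from the configured
#' Gaussians. The returned ground truth carries voxel-exact labels, exact
#' per-class tallies and the L3 slice index taken from the construction
#' geometry. Bit-identical under a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a `ct_volume`) and `truth`
#'   (a `ground_truth`).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  sp <- spec$spacing
  L <- spec$body_length
  tr <- spec$torso_radii
  pad_xy <- 10
  pad_z <- 10
  half_x <- max(tr$pelvis[1], tr$thorax[1], tr$leg_offset + tr$legs_r) + pad_xy
  half_y <- max(tr$pelvis[2], tr$thorax[2], tr$head[2]) + pad_xy
  nx <- ceiling(2 * half_x / sp[1])
  ny <- ceiling(2 * half_y / sp[2])
  nz <- ceiling((L + 2 * pad_z) / sp[3])
  xc <- (seq_len(nx) - 0.5) * sp[1] - half_x
  yc <- (seq_len(ny) - 0.5) * sp[2] - half_y
  zc <- (seq_len(nz) - 0.5) * sp[3] - pad_z  # body coordinate: 0 at feet
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  inside <- function(cx, cy, a, b) ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
  ts <- spec$subcutaneous_thickness
  tm <- spec$muscle_thickness
  s_organ <- sqrt(1 - spec$visceral_fat_fraction)
  f <- .station_fractions * L
  an <- .anat

  torso_slice <- function(a, b, station) {
    code <- matrix(.TC[["air"]], nx, ny)
    outer <- inside(0, 0, a, b)
    in1 <- inside(0, 0, a - ts, b - ts)       # inner edge of fat ring
    in2 <- inside(0, 0, a - ts - tm, b - ts - tm)  # inner edge of muscle
    code[outer & !in1] <- .TC[["fat_sub"]]
    code[in1 & !in2] <- .TC[["muscle"]]
    a2 <- a - ts - tm
    b2 <- b - ts - tm
    if (station %in% c("pelvis", "abdomen")) {
      organ <- inside(0, 0, s_organ * a2, s_organ * b2)
      code[in2 & !organ] <- .TC[["fat_visc"]]
      code[in2 & organ] <- .TC[["organ"]]
      spine <- inside(0, -0.62 * b2, an$spine_r, an$spine_r)
      code[in2 & spine] <- .TC[["bone"]]
      if (station == "pelvis") {
        pb <- inside(an$pelvic_bone_cx, an$pelvic_bone_cy,
                     an$pelvic_bone[["a"]], an$pelvic_bone[["b"]]) |
              inside(-an$pelvic_bone_cx, an$pelvic_bone_cy,
                     an$pelvic_bone[["a"]], an$pelvic_bone[["b"]])
        code[in2 & pb] <- .TC[["bone"]]
      }
    } else if (station == "thorax") {
      ribs_in <- inside(0, 0, a2 - an$rib_thickness, b2 - an$rib_thickness)
      code[in2 & !ribs_in] <- .TC[["bone"]]
      code[ribs_in] <- .TC[["organ"]]
      lung <- inside(an$lung_cx, an$lung_cy, an$lung[["a"]], an$lung[["b"]]) |
              inside(-an$lung_cx, an$lung_cy, an$lung[["a"]], an$lung[["b"]])
      code[ribs_in & lung] <- .TC[["lung"]]
      spine <- inside(0, -0.62 * (b2 - an$rib_thickness),
                      an$spine_r, an$spine_r)
      code[ribs_in & spine] <- .TC[["bone"]]
    }
    code
  }

  leg_slice <- function() {
    code <- matrix(.TC[["air"]], nx, ny)
    for (cx in c(-tr$leg_offset, tr$leg_offset)) {
      outer <- inside(cx, 0, tr$legs_r, tr$legs_r)
      in1 <- inside(cx, 0, tr$legs_r - ts, tr$legs_r - ts)
      femur <- inside(cx, 0, an$femur_r, an$femur_r)
      code[outer & !in1] <- .TC[["fat_sub"]]
      code[in1 & !femur] <- .TC[["muscle"]]
      code[femur] <- .TC[["bone"]]
    }
    code
  }

  neck_slice <- function() {
    code <- matrix(.TC[["air"]], nx, ny)
    outer <- inside(0, 0, tr$neck_r, tr$neck_r)
    in1 <- inside(0, 0, tr$neck_r - ts, tr$neck_r - ts)
    spine <- inside(0, -8, an$spine_r, an$spine_r)
    code[outer & !in1] <- .TC[["fat_sub"]]
    code[in1 & !spine] <- .TC[["muscle"]]
    code[in1 & spine] <- .TC[["bone"]]
    code
  }

  head_slice <- function() {
    code <- matrix(.TC[["air"]], nx, ny)
    a <- tr$head[1]; b <- tr$head[2]
    outer <- inside(0, 0, a, b)
    in1 <- inside(0, 0, a - ts, b - ts)
    in2 <- inside(0, 0, a - ts - an$skull_thickness,
                  b - ts - an$skull_thickness)
    code[outer & !in1] <- .TC[["fat_sub"]]
    code[in1 & !in2] <- .TC[["bone"]]
    code[in2] <- .TC[["organ"]]
    code
  }

  # Station templates are z-invariant; build each once and reuse.
  tpl <- list(
    legs = leg_slice(),
    pelvis = torso_slice(tr$pelvis[1], tr$pelvis[2], "pelvis"),
    abdomen = torso_slice(tr$abdomen[1], tr$abdomen[2], "abdomen"),
    thorax = torso_slice(tr$thorax[1], tr$thorax[2], "thorax"),
    neck = neck_slice(),
    head = head_slice())
  station_of <- function(zb) {
    if (zb < 0 || zb > L) return(NA_character_)
    if (zb < f[["ischium"]]) "legs"
    else if (zb < f[["iliac"]]) "pelvis"
    else if (zb < f[["diaphragm"]]) "abdomen"
    else if (zb < f[["shoulder"]]) "thorax"
    else if (zb < f[["neck_top"]]) "neck"
    else "head"
  }
  codem <- matrix(.TC[["air"]], nx * ny, nz)
  tplv <- lapply(tpl, as.vector)
  for (k in seq_len(nz)) {
    st <- station_of(zc[k])
    if (!is.na(st)) codem[, k] <- tplv[[st]]
  }
  codes <- array(codem, dim = c(nx, ny, nz))

  # HU draw: one Gaussian per class, vectorized over the whole grid.
  hp <- spec$hu_params
  mu <- setNames(hp$mean, hp$class)
  sg <- setNames(hp$sd, hp$class)
  cls_of_code <- c("air", "lung", "organ", "bone", "muscle", "fat", "fat")
  idx <- as.integer(codes) + 1L
  mu_v <- unname(mu[cls_of_code])[idx]
  sg_v <- unname(sg[cls_of_code])[idx]
  hu <- with_seed(spec$seed, rnorm(length(idx), mean = mu_v, sd = sg_v))
  hu[hu < -1024] <- -1024
  hu[hu > 3071] <- 3071
  voxels <- array(hu, dim = dim(codes))

  lm_mm <- landmarks_mm(spec)
  z_to_idx <- function(z) {
    k <- which.min(abs(zc - z))
    as.integer(k)
  }
  landmarks <- vapply(lm_mm, z_to_idx, integer(1))

  # code -> label lookup: air, lung, organ, bone, muscle, fat_sub, fat_visc
  lab_of_code <- c(GT_LABELS[["background"]], GT_LABELS[["other_tissue"]],
                   GT_LABELS[["other_tissue"]], GT_LABELS[["other_tissue"]],
                   GT_LABELS[["muscle"]], GT_LABELS[["subcutaneous_fat"]],
                   GT_LABELS[["visceral_fat"]])
  labels <- array(lab_of_code[idx], dim = dim(codes))

  volume <- ct_volume(voxels, spacing = sp, field = "whole_body",
                      height_m = spec$height_m, landmarks = as.list(landmarks))
  truth <- ground_truth(labels, L3_slice_index = landmarks[["L3"]])
  list(volume = volume, truth = truth)
}

#' CT volume container
#'
#' @param voxels 3D numeric array of Hounsfield units, `[x, y, z]`, axial
#'   index increasing toward the head (1-based).
#' @param spacing Voxel spacing `c(x, y, z)` in mm.
#' @param field Acquisition field: `"whole_body"`, `"thorax_abdomen_pelvis"`
#'   or `"abdomen_pelvis"`.
#' @param height_m Patient height in metres.
#' @param landmarks Optional named list of landmark slice indices
#'   (construction metadata for phantoms).
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing, field = "whole_body", height_m = NA,
                      landmarks = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  field <- match.arg(field,
                     c("whole_body", "thorax_abdomen_pelvis", "abdomen_pelvis"))
  if (any(spacing <= 0)) stop("spacing components must be > 0", call. = FALSE)
  if (dim(voxels)[3] < 1L) stop("need at least one axial slice", call. = FALSE)
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071) {
    stop("HU values must lie in [-1024, 3071]", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 field = field, height_m = height_m, landmarks = landmarks),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, field %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "x"), x$field))
  invisible(x)
}

#' Ground-truth label container
#'
#' @param labels 3D integer array of [GT_LABELS] codes, congruent with the
#'   source volume.
#' @param L3_slice_index Axial index of the L3 vertebral level (1-based).
#' @return A `ground_truth` object with exact per-class voxel counts.
#' @export
ground_truth <- function(labels, L3_slice_index) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  counts <- vapply(GT_LABELS, function(code) sum(labels == code), numeric(1))
  structure(list(labels = labels, counts = counts,
                 L3_slice_index = as.integer(L3_slice_index)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> voxel counts:\n")
  print(x$counts)
  cat("L3 slice index:", x$L3_slice_index, "\n")
  invisible(x)
}

#' Crop a whole-body phantom to an acquisition field
#'
#' Extracts the axial sub-range of a whole-body volume corresponding to a
#' clinical acquisition field. Abdomino-pelvic fields run from the ischium
#' landmark to the diaphragm plus a 30 mm margin (lung bases included, as on
#' clinical acquisitions); thoraco-abdomino-pelvic fields run from the
#' ischium to the shoulder landmark. Landmark indices and the ground-truth
#' L3 index are offset into the cropped frame; tallies are recomputed over
#' the kept range.
#'
#' @param volume A whole-body `ct_volume` with landmarks.
#' @param truth The matching `ground_truth`.
#' @param field `"abdomen_pelvis"` or `"thorax_abdomen_pelvis"`.
#' @return A list with cropped `volume` and `truth`.
#' @export
crop_field <- function(volume, truth,
                       field = c("abdomen_pelvis", "thorax_abdomen_pelvis")) {
  field <- match.arg(field)
  if (volume$field != "whole_body") {
    stop("crop_field() expects a whole-body volume", call. = FALSE)
  }
  lm <- volume$landmarks
  if (is.null(lm)) stop("volume carries no landmarks", call. = FALSE)
  dz <- volume$spacing[3]
  margin_slices <- ceiling(.anat$field_margin_mm / dz)
  from <- lm$ischium
  to <- if (field == "abdomen_pelvis") lm$diaphragm + margin_slices
        else lm$shoulder
  nz <- dim(volume$voxels)[3]
  if (from < 1L || to > nz) {
    stop("requested field exceeds the volume's axial extent", call. = FALSE)
  }
  out <- crop_slices(volume, truth, from, to)
  out$volume$field <- field
  out
}

#' Crop a volume and its ground truth to an axial slice range
#'
#' Lower-level crop used by [crop_field()]; keeps slices `from:to`
#' (inclusive, 1-based) and offsets landmark and L3 indices into the new
#' frame (dropped landmarks become `NA`).
#'
#' @inheritParams crop_field
#' @param from,to First and last axial slice to keep.
#' @return A list with cropped `volume` and `truth`.
#' @export
crop_slices <- function(volume, truth, from, to) {
  nz <- dim(volume$voxels)[3]
  from <- as.integer(from); to <- as.integer(to)
  if (from < 1L || to > nz || from > to) {
    stop("invalid axial range [", from, ", ", to, "]", call. = FALSE)
  }
  shift <- function(idx) {
    new <- idx - from + 1L
    if (is.na(new) || new < 1L || new > (to - from + 1L)) NA_integer_
    else as.integer(new)
  }
  lm <- volume$landmarks
  if (!is.null(lm)) lm <- lapply(lm, shift)
  vol <- ct_volume(volume$voxels[, , from:to, drop = FALSE],
                   spacing = volume$spacing, field = volume$field,
                   height_m = volume$height_m, landmarks = lm)
  tr <- ground_truth(truth$labels[, , from:to, drop = FALSE],
                     L3_slice_index = shift(truth$L3_slice_index))
  list(volume = vol, truth = tr)
}
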