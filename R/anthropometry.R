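# Whole-body mass model: voxel tallies -> masses via tissue densities and
# atlas-derived adaptive extrapolation factors, normalized by height^2;
# plus the matching single-slice L3 area measures.

#' Mass-model constants
#'
#' Tissue densities and voxel volume used by the 3D mass model. Densities
#' default to the reference values 1.06 g/mL for skeletal muscle and
#' 0.923 g/mL for adipose tissue.
#'
#' @param spacing Voxel spacing `c(x, y, z)` in mm; the voxel volume is
#'   `prod(spacing) / 1000` mL.
#' @param rho_muscle,rho_fat Tissue densities in g/mL.
#' @return A `mass_constants` object with `rho_muscle`, `rho_fat` and
#'   `v_voxel_ml`.
#' @export
mass_constants <- function(spacing, rho_muscle = 1.06, rho_fat = 0.923) {
  if (any(spacing <= 0)) stop("spacing components must be > 0", call. = FALSE)
  stop_if_not_scalar_pos(rho_muscle, "rho_muscle")
  stop_if_not_scalar_pos(rho_fat, "rho_fat")
  structure(list(rho_muscle = rho_muscle, rho_fat = rho_fat,
                 v_voxel_ml = prod(spacing) / 1000),
            class = "mass_constants")
}

#' Extrapolation factor container
#'
#' One unitless factor per tissue converting within-field voxel tallies to
#' whole-body tallies. Each factor is >= 1; a whole-body field has all
#' factors exactly 1.
#'
#' @param k_muscle,k_subcutaneous_fat,k_visceral_fat Factors (>= 1).
#' @param field Acquisition field the factors apply to.
#' @param atlas_size Number of atlas subjects behind the factors.
#' @return An `extrapolation_factors` object.
#' @export
extrapolation_factors <- function(k_muscle, k_subcutaneous_fat,
                                  k_visceral_fat,
                                  field = "whole_body", atlas_size = 0L) {
  k <- c(muscle = k_muscle, subcutaneous_fat = k_subcutaneous_fat,
         visceral_fat = k_visceral_fat)
  if (any(!is.finite(k)) || any(k < 1 - 1e-9)) {
    stop("extrapolation factors must be finite and >= 1", call. = FALSE)
  }
  if (field == "whole_body" && any(abs(k - 1) > 1e-12)) {
    stop("whole-body factors must equal 1 exactly", call. = FALSE)
  }
  structure(list(k = k, field = field, atlas_size = as.integer(atlas_size)),
            class = "extrapolation_factors")
}

#' @export
print.extrapolation_factors <- function(x, ...) {
  cat(sprintf("<extrapolation_factors> field %s (atlas n = %d)\n",
              x$field, x$atlas_size))
  print(signif(x$k, 5))
  invisible(x)
}

#' Build an atlas entry from whole-body and field-cropped tallies
#'
#' @param truth_whole,truth_cropped `ground_truth` objects (or named count
#'   vectors) for the same subject before and after field cropping.
#' @return List with `whole` and `cropped` tissue counts.
#' @export
atlas_entry <- function(truth_whole, truth_cropped) {
  pick <- function(x) {
    counts <- if (inherits(x, "ground_truth")) x$counts
              else if (inherits(x, "tissue_masks")) x$counts
              else x
    counts[c("muscle", "subcutaneous_fat", "visceral_fat")]
  }
  list(whole = pick(truth_whole), cropped = pick(truth_cropped))
}

#' Derive adaptive extrapolation factors from a CT atlas
#'
#' Each factor is the arithmetic mean, over atlas subjects, of the ratio of
#' whole-body voxels of the tissue to the voxels of that tissue inside the
#' acquired body area.
#'
#' @param atlas List of [atlas_entry()] objects.
#' @param field Acquisition field the factors are for; `"whole_body"`
#'   returns unit factors without consulting the atlas.
#' @return An [extrapolation_factors()] object.
#' @export
build_extrapolation_factors <- function(atlas = list(),
                                        field = c("abdomen_pelvis",
                                                  "thorax_abdomen_pelvis",
                                                  "whole_body")) {
  field <- match.arg(field)
  if (field == "whole_body") {
    return(extrapolation_factors(1, 1, 1, field = "whole_body",
                                 atlas_size = length(atlas)))
  }
  if (!length(atlas)) stop("atlas must contain at least one entry",
                           call. = FALSE)
  tissues <- c("muscle", "subcutaneous_fat", "visceral_fat")
  ratios <- vapply(seq_along(atlas), function(i) {
    e <- atlas[[i]]
    if (any(e$cropped[tissues] == 0)) {
      stop("atlas entry ", i, " has a zero cropped tissue count",
           call. = FALSE)
    }
    e$whole[tissues] / e$cropped[tissues]
  }, numeric(3))
  k <- rowMeans(matrix(ratios, nrow = 3,
                       dimnames = list(tissues, NULL)))
  extrapolation_factors(k[["muscle"]], k[["subcutaneous_fat"]],
                        k[["visceral_fat"]], field = field,
                        atlas_size = length(atlas))
}

tissue_count_vector <- function(masks) {
  counts <- if (inherits(masks, "tissue_masks")) masks$counts
            else if (inherits(masks, "ground_truth")) masks$counts
            else masks
  need <- c("muscle", "subcutaneous_fat", "visceral_fat")
  if (!all(need %in% names(counts))) {
    stop("tissue counts must name muscle, subcutaneous_fat, visceral_fat",
         call. = FALSE)
  }
  counts <- counts[need]
  if (any(counts < 0)) stop("tissue counts must be >= 0", call. = FALSE)
  counts
}

#' Compute whole-body tissue masses
#'
#' The 3D mass model: each raw mass is
#' `N_tissue * k_tissue * V_voxel * rho_tissue` (grams, reported in kg),
#' with muscle density for the muscle compartment and fat density for both
#' fat compartments; total fat mass is the sum of the visceral and
#' subcutaneous masses; all masses are also reported normalized by the
#' squared body height (kg/m2).
#'
#' @param masks A [tissue_masks()], `ground_truth`, or named count vector
#'   (`muscle`, `subcutaneous_fat`, `visceral_fat`).
#' @param k An [extrapolation_factors()] object.
#' @param constants A [mass_constants()] object.
#' @param height_m Body height in metres.
#' @return A `mass_result`: `raw_kg` and `normalized` vectors named
#'   `VFM3D`, `SFM3D`, `FBM3D`, `MBM3D`, plus the inputs used.
#' @export
compute_masses <- function(masks, k, constants, height_m) {
  stop_if_not_scalar_pos(height_m, "height_m")
  stopifnot(inherits(k, "extrapolation_factors"),
            inherits(constants, "mass_constants"))
  n <- tissue_count_vector(masks)
  v <- constants$v_voxel_ml
  raw <- c(
    VFM3D = n[["visceral_fat"]] * k$k[["visceral_fat"]] * v *
      constants$rho_fat / 1000,
    SFM3D = n[["subcutaneous_fat"]] * k$k[["subcutaneous_fat"]] * v *
      constants$rho_fat / 1000,
    MBM3D = n[["muscle"]] * k$k[["muscle"]] * v * constants$rho_muscle / 1000)
  raw <- c(raw, FBM3D = unname(raw[["VFM3D"]] + raw[["SFM3D"]]))
  ord <- c("VFM3D", "SFM3D", "FBM3D", "MBM3D")
  raw <- raw[ord]
  structure(list(raw_kg = raw, normalized = raw / height_m^2,
                 height_m = height_m, k = k, constants = constants,
                 counts = n),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat("<mass_result> raw (kg):\n")
  print(signif(x$raw_kg, 4))
  cat(sprintf("normalized (kg/m2, height %.2f m):\n", x$height_m))
  print(signif(x$normalized, 4))
  invisible(x)
}

#' Compute L3-level cross-sectional areas
#'
#' Single-slice counterparts of the 3D masses: per-tissue cross-sectional
#' area at the L3 vertebral level (voxel count in the slice times in-plane
#' pixel area, reported in cm2), total fat area as the sum of visceral and
#' subcutaneous areas, and all areas normalized for stature (cm2/m2).
#'
#' @param masks A [tissue_masks()] object.
#' @param l3_index Axial index of the L3 slice (1-based).
#' @param spacing Voxel spacing (mm).
#' @param height_m Body height in metres.
#' @return An `area_result`: `raw_cm2` and `normalized` vectors named
#'   `VFA2D`, `SFA2D`, `FBA2D`, `MBA2D`.
#' @export
compute_l3_areas <- function(masks, l3_index, spacing, height_m) {
  stop_if_not_scalar_pos(height_m, "height_m")
  stopifnot(inherits(masks, "tissue_masks"))
  nz <- dim(masks$muscle)[3]
  if (is.na(l3_index) || l3_index < 1L || l3_index > nz) {
    stop("L3 index ", l3_index, " outside the axial range [1, ", nz, "]",
         call. = FALSE)
  }
  px_cm2 <- spacing[1] * spacing[2] / 100
  raw <- c(
    VFA2D = sum(masks$visceral_fat[, , l3_index]) * px_cm2,
    SFA2D = sum(masks$subcutaneous_fat[, , l3_index]) * px_cm2,
    MBA2D = sum(masks$muscle[, , l3_index]) * px_cm2)
  raw <- c(raw, FBA2D = unname(raw[["VFA2D"]] + raw[["SFA2D"]]))
  ord <- c("VFA2D", "SFA2D", "FBA2D", "MBA2D")
  raw <- raw[ord]
  structure(list(raw_cm2 = raw, normalized = raw / height_m^2,
                 height_m = height_m),
            class = "area_result")
}

#' Assemble the eight anthropometric parameters
#'
#' Combines a 3D [compute_masses()] result and a 2D [compute_l3_areas()]
#' result into a one-row data frame of the eight height-normalized
#' parameters plus the raw masses/areas.
#'
#' @param masses A `mass_result`.
#' @param areas An `area_result`.
#' @return One-row data frame with columns [anthro_parameters()], the raw
#'   values (`raw_` prefix) and `height_m`.
#' @export
anthro_result <- function(masses, areas) {
  stopifnot(inherits(masses, "mass_result"), inherits(areas, "area_result"))
  if (abs(masses$height_m - areas$height_m) > 1e-9) {
    stop("mass and area results use different heights", call. = FALSE)
  }
  out <- c(as.list(masses$normalized), as.list(areas$normalized),
           setNames(as.list(masses$raw_kg),
                    paste0("raw_", names(masses$raw_kg))),
           setNames(as.list(areas$raw_cm2),
                    paste0("raw_", names(areas$raw_cm2))),
           list(height_m = masses$height_m))
  as.data.frame(out)
}
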