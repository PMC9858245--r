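# NIfTI and CSV interfaces.

#' Write a CT volume as NIfTI
#'
#' Spacing is encoded in the NIfTI pixdim/affine; acquisition field, height
#' and landmarks go to a JSON sidecar (`<path>.json`).
#'
#' @param volume A `ct_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_ct_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  meta <- list(field = volume$field, height_m = volume$height_m,
               landmarks = volume$landmarks)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CT volume from NIfTI
#'
#' @param path Path written by [write_ct_volume()]; the JSON sidecar is
#'   consulted when present.
#' @return A `ct_volume`.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list()
  lm <- meta$landmarks
  if (!is.null(lm)) lm <- lapply(lm, as.integer)
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
            field = meta$field %||% "whole_body",
            height_m = as.numeric(meta$height_m %||% NA),
            landmarks = lm)
}

#' Write ground-truth (or predicted) labels as NIfTI
#'
#' One integer-coded label volume using the [GT_LABELS] coding.
#'
#' @param truth A `ground_truth` or `tissue_masks` object.
#' @param spacing Voxel spacing (mm).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(truth, spacing, path) {
  labels <- if (inherits(truth, "ground_truth")) {
    truth$labels
  } else if (inherits(truth, "tissue_masks")) {
    lab <- array(GT_LABELS[["background"]], dim(truth$muscle))
    lab[truth$muscle] <- GT_LABELS[["muscle"]]
    lab[truth$subcutaneous_fat] <- GT_LABELS[["subcutaneous_fat"]]
    lab[truth$visceral_fat] <- GT_LABELS[["visceral_fat"]]
    lab
  } else stop("unsupported label source", call. = FALSE)
  img <- RNifti::asNifti(labels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read an integer label volume
#'
#' @param path NIfTI path.
#' @param L3_slice_index Optional L3 index to record on the result.
#' @return A `ground_truth`.
#' @export
read_label_volume <- function(path, L3_slice_index = NA_integer_) {
  img <- RNifti::readNifti(path)
  ground_truth(array(as.integer(img), dim = dim(img)),
               L3_slice_index = L3_slice_index)
}

#' Write a cohort table as CSV
#'
#' Plain CSV with a documented header (see [generate_cohort()] for the
#' column contract).
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with the [generate_cohort()] column contract.
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("os_months", "event")
  if (!all(need %in% names(d))) {
    stop("cohort CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("sex" %in% names(d)) d$sex <- factor(d$sex,
                                           levels = c("male", "female"))
  if ("cancer_type" %in% names(d)) d$cancer_type <- factor(d$cancer_type)
  class(d) <- c("cohort_table", "data.frame")
  d
}
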