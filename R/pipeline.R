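#' Run the full PET/CT index pipeline
#'
#' Composes the stages of the tumor-burden measurement: Gaussian smoothing
#' of the SUV volume (sigma 2 mm by default), SUV-threshold hotspot
#' detection by 3D connected components, removal of hotspots with no bone
#' overlap (the bone mask is resampled onto the PET grid by nearest
#' neighbour when the grids differ), optional manual classification, and
#' the index computation.
#'
#' Two operating modes mirror the two published variants:
#' \describe{
#'   \item{auto}{fully automated, threshold SUV 15 by default; every
#'     bone-overlapping hotspot is included, no labels accepted.}
#'   \item{manual}{a reader-chosen threshold (plausible range 4-12, a
#'     warning is emitted outside it; published per-patient choices ranged
#'     over SUV 6-9) plus an optional per-hotspot classification table;
#'     `benign` hotspots are excluded.}
#' }
#'
#' The bone-volume denominator is measured on the mask's native grid;
#' the resampled mask is used only for the overlap test.
#'
#' @param suv an `suv_map`.
#' @param bone a `bone_mask` (any grid overlapping the PET volume).
#' @param mode `"auto"` or `"manual"`.
#' @param threshold_suv detection threshold; defaults to 15 in auto mode,
#'   required in manual mode.
#' @param sigma_mm smoothing standard deviation in mm (default 2).
#' @param labels optional labels data frame (manual mode only).
#' @param skeletal_fraction see [compute_index()].
#' @param volume_mode see [filter_by_bone_overlap()].
#' @param unlabeled see [apply_classification()].
#' @return A list with elements `index` (an `index_result`), `hotspots`
#'   (the included `hotspot_set`) and `detected` (the pre-filter set).
#' @export
run_pipeline <- function(suv, bone, mode = c("auto", "manual"),
                         threshold_suv = NULL, sigma_mm = 2,
                         labels = NULL, skeletal_fraction = 0.33,
                         volume_mode = c("full", "intersection"),
                         unlabeled = c("metastasis", "strict")) {
  mode <- match.arg(mode)
  volume_mode <- match.arg(volume_mode)
  stopifnot(inherits(suv, "image_volume"), inherits(bone, "bone_mask"))
  if (is.null(threshold_suv)) {
    if (mode == "auto") threshold_suv <- 15
    else stop("manual mode requires an explicit 'threshold_suv'",
              call. = FALSE)
  }
  if (mode == "auto" && !is.null(labels))
    stop("auto mode accepts no classification labels", call. = FALSE)
  if (mode == "manual" && (threshold_suv < 4 || threshold_suv > 12))
    warning("manual threshold ", threshold_suv,
            " outside the plausible range [4, 12]")

  vbone <- bone_volume_mm3(bone)
  if (vbone <= 0)
    stop("bone mask is empty; the index denominator would be zero",
         call. = FALSE)
  smoothed <- gaussian_smooth(suv, sigma_mm)
  detected <- detect_hotspots(smoothed, threshold_suv)
  bone_pet <- if (same_grid(bone, suv)) bone else
    resample_mask_to_grid(bone, grid_of(suv))
  kept <- filter_by_bone_overlap(detected, bone_pet, volume_mode)
  if (mode == "manual" && !is.null(labels))
    kept <- apply_classification(kept, labels, match.arg(unlabeled))
  included <- included_hotspots(kept)
  idx <- compute_index(included, vbone, skeletal_fraction, mode = mode,
                       n_hotspots_detected = n_hotspots(detected),
                       sigma_mm = sigma_mm)
  list(index = idx, hotspots = included, detected = detected)
}

#' Rule-based bone mask from a CT volume
#'
#' A deliberately simple Hounsfield-threshold baseline for producing a
#' skeletal mask when no dedicated bone segmentation is available: voxels
#' above `hu_threshold` are kept and connected components smaller than
#' `min_component_mm3` are discarded as speckle.
#'
#' @param ct an `image_volume` in Hounsfield-like units.
#' @param hu_threshold HU cut for bone (default 200).
#' @param min_component_mm3 minimum component volume retained.
#' @return A `bone_mask` on the CT grid.
#' @export
baseline_bone_mask_from_ct <- function(ct, hu_threshold = 200,
                                       min_component_mm3 = 500) {
  stopifnot(inherits(ct, "image_volume"))
  fg <- ct$values > hu_threshold
  out <- array(0, dim(ct$values))
  if (any(fg)) {
    lab <- label_components_3d(fg, 26L)
    vv <- voxel_volume_mm3(ct)
    for (vox in lab$voxels)
      if (length(vox) * vv >= min_component_mm3) out[vox] <- 1
  }
  bone_mask(out, ct$spacing_mm, ct$origin_mm)
}
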