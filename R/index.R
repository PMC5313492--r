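#' Compute the PET/CT skeletal tumor-burden index
#'
#' The index is the fraction of segmented bone volume occupied by included
#' hotspots, scaled to the whole skeleton and expressed in percent:
#'
#' `index_percent = 100 * skeletal_fraction * sum(v_i) / V_bone`
#'
#' where `v_i` are the volumes of the included (metastatic,
#' bone-overlapping) hotspots and `V_bone` the volume of the segmented
#' bones. The default `skeletal_fraction = 0.33` extrapolates from the
#' segmented axial bones — about a third of total skeletal volume — to the
#' full skeleton, so an index of 33% corresponds to hotspot volume equal
#' to the entire segmented bone volume.
#'
#' @param included a `hotspot_set` of index-eligible hotspots (see
#'   [included_hotspots()]).
#' @param bone_volume_mm3 segmented bone volume in mm^3 (> 0).
#' @param skeletal_fraction fraction of total skeletal volume covered by
#'   the segmented bones, in (0, 1].
#' @param mode `"manual"` or `"auto"`, recorded as provenance.
#' @param n_hotspots_detected number of hotspots before filtering,
#'   recorded as provenance (defaults to the included count).
#' @param sigma_mm smoothing sigma recorded as provenance.
#' @return An `index_result` with the index and its full provenance.
#' @examples
#' hs <- detect_hotspots(
#'   suv_map(array(c(20, rep(1, 26)), c(3, 3, 3)), c(10, 10, 10)), 15)
#' compute_index(hs, bone_volume_mm3 = 330000)
#' @export
compute_index <- function(included, bone_volume_mm3,
                          skeletal_fraction = 0.33,
                          mode = c("auto", "manual"),
                          n_hotspots_detected = NULL, sigma_mm = NA_real_) {
  stopifnot(inherits(included, "hotspot_set"))
  mode <- match.arg(mode)
  if (!is.numeric(bone_volume_mm3) || length(bone_volume_mm3) != 1L ||
      is.na(bone_volume_mm3) || bone_volume_mm3 <= 0)
    stop("'bone_volume_mm3' must be a single positive number (empty bone ",
         "masks cannot be normalized)", call. = FALSE)
  if (!is.numeric(skeletal_fraction) || skeletal_fraction <= 0 ||
      skeletal_fraction > 1)
    stop("'skeletal_fraction' must lie in (0, 1]", call. = FALSE)
  total <- sum(included$table$volume_mm3)
  n_inc <- n_hotspots(included)
  if (is.null(n_hotspots_detected)) n_hotspots_detected <- n_inc
  structure(list(
    mode = mode,
    threshold_suv = included$threshold_suv,
    sigma_mm = sigma_mm,
    n_hotspots_detected = as.integer(n_hotspots_detected),
    n_hotspots_included = as.integer(n_inc),
    total_hotspot_volume_mm3 = total,
    bone_volume_mm3 = bone_volume_mm3,
    skeletal_fraction = skeletal_fraction,
    index_percent = 100 * skeletal_fraction * total / bone_volume_mm3
  ), class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("PET/CT skeletal tumor-burden index (%s mode)\n", x$mode))
  cat(sprintf("  threshold SUV %s, sigma %s mm\n", format(x$threshold_suv),
              format(x$sigma_mm)))
  cat(sprintf("  hotspots: %d detected, %d included\n",
              x$n_hotspots_detected, x$n_hotspots_included))
  cat(sprintf("  hotspot volume %.1f mm^3 / bone volume %.1f mm^3\n",
              x$total_hotspot_volume_mm3, x$bone_volume_mm3))
  cat(sprintf("  index: %.4g%% (skeletal fraction %.2f)\n", x$index_percent,
              x$skeletal_fraction))
  invisible(x)
}

#' Write an index result (plus provenance) as JSON
#'
#' @param result an `index_result`.
#' @param path output path.
#' @param inputs optional named character vector of input file paths; MD5
#'   checksums are recorded.
#' @return `path` invisibly.
#' @export
write_index_json <- function(result, path, inputs = NULL) {
  stopifnot(inherits(result, "index_result"))
  obj <- unclass(result)
  obj$tool <- "pettbi"
  obj$version <- as.character(utils::packageVersion("pettbi"))
  if (!is.null(inputs)) {
    sums <- tools::md5sum(inputs)
    obj$input_checksums <- as.list(stats::setNames(unname(sums),
                                                   names(inputs)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
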