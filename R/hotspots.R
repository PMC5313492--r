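new_hotspot_set <- function(table, voxels, grid, threshold_suv, sigma_mm,
                            connectivity = 26L, comparison = ">") {
  structure(list(table = table, voxels = voxels, grid = grid,
                 threshold_suv = threshold_suv, sigma_mm = sigma_mm,
                 connectivity = connectivity, comparison = comparison),
            class = "hotspot_set")
}

empty_hotspot_table <- function() {
  data.frame(hotspot_id = integer(), voxel_count = integer(),
             volume_mm3 = numeric(), peak_suv = numeric(),
             centroid_x_mm = numeric(), centroid_y_mm = numeric(),
             centroid_z_mm = numeric(), overlaps_bone = logical(),
             label = character(), stringsAsFactors = FALSE)
}

#' Detect supra-threshold hotspots in an SUV volume
#'
#' Voxels whose (already smoothed) SUV exceeds `threshold_suv` are grouped
#' into 3D connected components; each component becomes one hotspot with
#' its voxel count, physical volume, peak SUV and world-space centroid.
#' Component ids are assigned 1..n by ascending minimum voxel index with
#' the slowest-varying axis ranking first, so ids are deterministic and a
#' manual classification file written for one run stays valid for the
#' next.
#'
#' @param suv_smoothed an `suv_map`, normally the output of
#'   [gaussian_smooth()].
#' @param threshold_suv positive SUV detection threshold; comparison is
#'   strict (`value > threshold`) by default.
#' @param connectivity 26 (default) or 6 neighbourhood for component
#'   labeling.
#' @param comparison `">"` (strict, default) or `">="`.
#' @return A `hotspot_set`: hotspot table plus per-hotspot voxel index
#'   sets, the source grid and the detection parameters.
#' @export
detect_hotspots <- function(suv_smoothed, threshold_suv, connectivity = 26L,
                            comparison = c(">", ">=")) {
  stopifnot(inherits(suv_smoothed, "image_volume"))
  comparison <- match.arg(comparison)
  if (!is.numeric(threshold_suv) || length(threshold_suv) != 1L ||
      is.na(threshold_suv) || threshold_suv <= 0)
    stop("'threshold_suv' must be a single positive number", call. = FALSE)
  vals <- suv_smoothed$values
  fg <- if (comparison == ">") vals > threshold_suv else vals >= threshold_suv
  grid <- grid_of(suv_smoothed)
  if (!any(fg)) {
    return(new_hotspot_set(empty_hotspot_table(), list(), grid,
                           threshold_suv, NA_real_, connectivity, comparison))
  }
  if (all(fg))
    warning("entire volume is above threshold: one hotspot spans the volume")
  lab <- label_components_3d(fg, connectivity)
  vv <- prod(grid$spacing_mm)
  d <- grid$dim
  rows <- lapply(seq_along(lab$voxels), function(i) {
    vox <- lab$voxels[[i]]
    co <- arrayInd(vox, d)
    cen <- grid$origin_mm + (colMeans(co) - 1) * grid$spacing_mm
    data.frame(hotspot_id = i, voxel_count = length(vox),
               volume_mm3 = length(vox) * vv, peak_suv = max(vals[vox]),
               centroid_x_mm = cen[1], centroid_y_mm = cen[2],
               centroid_z_mm = cen[3], overlaps_bone = NA,
               label = "unclassified", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new_hotspot_set(tab, lab$voxels, grid, threshold_suv, NA_real_,
                  connectivity, comparison)
}

#' Number of hotspots in a set
#' @param hs a `hotspot_set`.
#' @export
n_hotspots <- function(hs) nrow(hs$table)

#' Hotspot table as a data frame
#' @param x a `hotspot_set`.
#' @param ... unused.
#' @export
as.data.frame.hotspot_set <- function(x, ...) x$table

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> %d hotspot(s), threshold SUV %s (%s), %d-connectivity\n",
              n_hotspots(x), format(x$threshold_suv), x$comparison,
              x$connectivity))
  if (n_hotspots(x) > 0) print(x$table, row.names = FALSE)
  invisible(x)
}

subset_hotspots <- function(hs, keep) {
  hs$table <- hs$table[keep, , drop = FALSE]
  rownames(hs$table) <- NULL
  hs$voxels <- hs$voxels[keep]
  hs
}

#' Remove hotspots that do not overlap the skeleton
#'
#' A hotspot is kept when at least one of its voxels lies inside the bone
#' mask (which must live on the same grid as the hotspots — resample it
#' first with [resample_mask_to_grid()] if needed). Under the default
#' `volume_mode = "full"` a kept hotspot retains its complete volume even
#' when it straddles the bone boundary; under `"intersection"` its voxel
#' set and volume are restricted to the bone-overlapping part.
#'
#' @param hotspots a `hotspot_set`.
#' @param bone_on_pet_grid a `bone_mask` on the hotspot grid.
#' @param volume_mode `"full"` or `"intersection"`.
#' @return The filtered `hotspot_set`; surviving hotspots keep their
#'   original ids and gain `overlaps_bone = TRUE`.
#' @export
filter_by_bone_overlap <- function(hotspots, bone_on_pet_grid,
                                   volume_mode = c("full", "intersection")) {
  stopifnot(inherits(hotspots, "hotspot_set"),
            inherits(bone_on_pet_grid, "bone_mask"))
  volume_mode <- match.arg(volume_mode)
  if (!same_grid(hotspots$grid, bone_on_pet_grid))
    stop("bone mask grid does not match the hotspot grid; resample first",
         call. = FALSE)
  if (n_hotspots(hotspots) == 0L) return(hotspots)
  inbone <- bone_on_pet_grid$values != 0
  overlap <- vapply(hotspots$voxels, function(v) sum(inbone[v]), numeric(1))
  keep <- overlap >= 1
  out <- subset_hotspots(hotspots, keep)
  if (n_hotspots(out) > 0L) {
    out$table$overlaps_bone <- TRUE
    if (volume_mode == "intersection") {
      vv <- prod(out$grid$spacing_mm)
      out$voxels <- lapply(out$voxels, function(v) v[inbone[v]])
      out$table$voxel_count <- vapply(out$voxels, length, integer(1))
      out$table$volume_mm3 <- out$table$voxel_count * vv
    }
  }
  out
}

#' Apply manual hotspot classification labels
#'
#' Attaches reader labels (`metastasis` or `benign`) to detected hotspots,
#' mirroring the manual reading workflow in which hotspots judged to stem
#' from degeneration, inflammation or fractures are excluded from the
#' tumor-burden index. By default hotspots absent from the label table are
#' treated as `metastasis` with a warning, so a labels file need only list
#' the exclusions; `unlabeled = "strict"` demands a complete table.
#'
#' @param hotspots a `hotspot_set`.
#' @param labels data frame with columns `hotspot_id` and `label`
#'   (values `"metastasis"` or `"benign"`).
#' @param unlabeled `"metastasis"` (default, warn) or `"strict"` (error on
#'   incomplete labels).
#' @return The labeled `hotspot_set`.
#' @export
apply_classification <- function(hotspots, labels,
                                 unlabeled = c("metastasis", "strict")) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  unlabeled <- match.arg(unlabeled)
  if (!is.data.frame(labels) ||
      !all(c("hotspot_id", "label") %in% names(labels)))
    stop("'labels' must have columns hotspot_id and label", call. = FALSE)
  ids <- as.integer(labels$hotspot_id)
  lab <- as.character(labels$label)
  if (anyDuplicated(ids))
    stop("duplicate hotspot_id in labels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bad <- setdiff(ids, hotspots$table$hotspot_id)
  if (length(bad))
    stop("labels reference unknown hotspot_id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(lab %in% c("metastasis", "benign")))
    stop("labels must be 'metastasis' or 'benign'", call. = FALSE)
  m <- match(hotspots$table$hotspot_id, ids)
  unl <- is.na(m)
  if (any(unl)) {
    if (unlabeled == "strict")
      stop("unlabeled hotspot_id(s) in strict mode: ",
           paste(hotspots$table$hotspot_id[unl], collapse = ", "),
           call. = FALSE)
    warning(sum(unl), " unlabeled hotspot(s) treated as metastasis")
  }
  hotspots$table$label <- ifelse(unl, "metastasis", lab[m])
  hotspots
}

#' Hotspots eligible for the index
#'
#' Everything not labeled `benign`: in automated mode nothing is labeled
#' and every bone-overlapping hotspot counts; in manual mode only
#' metastasis-labeled (or defaulted) hotspots survive.
#'
#' @param hotspots a `hotspot_set`.
#' @return A `hotspot_set` restricted to index-eligible hotspots.
#' @export
included_hotspots <- function(hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  subset_hotspots(hotspots, hotspots$table$label != "benign")
}

#' Write / read the hotspot table as CSV
#'
#' @param hs a `hotspot_set`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_hotspot_csv <- function(hs, path) {
  utils::write.csv(as.data.frame(hs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a manual classification labels CSV
#'
#' Expected header: `hotspot_id,label` with label in
#' \{metastasis, benign\}.
#'
#' @param path CSV path.
#' @return Data frame with integer `hotspot_id` and character `label`.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("hotspot_id", "label") %in% names(df)))
    stop("labels CSV must have columns hotspot_id,label", call. = FALSE)
  df$hotspot_id <- as.integer(df$hotspot_id)
  df$label <- trimws(df$label)
  df
}
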