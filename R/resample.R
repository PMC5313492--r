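#' Resample a binary mask onto another grid
#'
#' Nearest-neighbour resampling by world coordinates: each target voxel
#' takes the value of the source voxel whose center is closest to the
#' target voxel center. Because both grids are axis-aligned the lookup is
#' separable per axis. Target voxels whose nearest source center falls
#' outside the source lattice are set to 0.
#'
#' The typical use is bringing a CT-resolution bone mask onto the coarser
#' PET grid before [filter_by_bone_overlap()].
#'
#' @param mask a `bone_mask`.
#' @param target an `image_volume` (or grid descriptor) defining the
#'   output lattice.
#' @return A `bone_mask` on the target grid.
#' @export
resample_mask_to_grid <- function(mask, target) {
  stopifnot(inherits(mask, "bone_mask"))
  tg <- if (inherits(target, "image_volume")) grid_of(target) else target
  sg <- grid_of(mask)
  maps <- vector("list", 3)
  any_inside <- TRUE
  for (a in 1:3) {
    w <- axis_world(tg, a)
    # nearest source index; floor(x + 0.5) for platform-stable ties
    i <- floor((w - sg$origin_mm[a]) / sg$spacing_mm[a] + 0.5) + 1
    inside <- i >= 1 & i <= sg$dim[a]
    if (!any(inside)) any_inside <- FALSE
    maps[[a]] <- list(idx = pmin(pmax(as.integer(i), 1L), sg$dim[a]),
                      inside = inside)
  }
  if (!any_inside)
    warning("target grid lies entirely outside the mask extent; empty mask")
  out <- mask$values[maps[[1]]$idx, maps[[2]]$idx, maps[[3]]$idx, drop = FALSE]
  dim(out) <- tg$dim
  # zero voxels mapped from outside the source extent
  out <- out *
    outer(outer(as.numeric(maps[[1]]$inside), as.numeric(maps[[2]]$inside)),
          as.numeric(maps[[3]]$inside))
  dim(out) <- tg$dim
  bone_mask(out, tg$spacing_mm, tg$origin_mm)
}
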