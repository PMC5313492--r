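#' Construct a 3D image volume with physical geometry
#'
#' An `image_volume` is the carrier for all gridded data in this package:
#' SUV maps, CT volumes and binary masks. It couples a 3D numeric array
#' with the voxel spacing (mm per voxel edge, one value per array axis)
#' and the world position of the *center* of voxel `[1,1,1]`. Array axis 1
#' is the fastest-varying axis in memory; axis 3 the slowest
#' (superior-inferior by convention).
#'
#' @param values 3D numeric array, all entries finite.
#' @param spacing_mm numeric length-3, per-axis voxel edge length in mm
#'   (all > 0).
#' @param origin_mm numeric length-3, world coordinate (mm) of the center
#'   of voxel `[1,1,1]`.
#' @return An object of class `image_volume` (a list with elements
#'   `values`, `spacing_mm`, `origin_mm`).
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), spacing_mm = c(2, 2, 3))
#' voxel_volume_mm3(vol)
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' contains non-finite entries", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive finite values", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite values", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "image_volume")
}

#' Construct an SUV map
#'
#' A body-weight-normalized standardized-uptake-value volume; values are
#' dimensionless and must be non-negative.
#'
#' @inheritParams image_volume
#' @return An object of class `c("suv_map", "image_volume")`.
#' @export
suv_map <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  vol <- image_volume(values, spacing_mm, origin_mm)
  if (any(vol$values < 0))
    stop("SUV values must be non-negative", call. = FALSE)
  class(vol) <- c("suv_map", class(vol))
  vol
}

#' Construct a binary bone mask
#'
#' @inheritParams image_volume
#' @param values 3D array of 0/1 values (logical accepted).
#' @return An object of class `c("bone_mask", "image_volume")`.
#' @export
bone_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (is.logical(values)) {
    dm <- dim(values)
    values <- array(as.double(values), dm)
  }
  vol <- image_volume(values, spacing_mm, origin_mm)
  if (!all(vol$values %in% c(0, 1)))
    stop("bone mask values must all be 0 or 1", call. = FALSE)
  class(vol) <- c("bone_mask", class(vol))
  vol
}

#' Voxel volume in cubic millimetres
#' @param vol an `image_volume`.
#' @return Scalar, product of the three spacing components.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing_mm)

#' Total bone volume of a mask in cubic millimetres
#' @param mask a `bone_mask`.
#' @return Number of 1-voxels times the voxel volume.
#' @export
bone_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "bone_mask"))
  sum(mask$values) * voxel_volume_mm3(mask)
}

# Grid descriptor: geometry without the payload. Used to compare and
# resample between lattices.
grid_of <- function(vol) {
  list(dim = dim(vol$values), spacing_mm = vol$spacing_mm,
       origin_mm = vol$origin_mm)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "image_volume")) grid_of(a) else a
  gb <- if (inherits(b, "image_volume")) grid_of(b) else b
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing_mm - gb$spacing_mm) < tol) &&
    all(abs(ga$origin_mm - gb$origin_mm) < tol)
}

# World coordinates (mm) of voxel centers along one axis.
axis_world <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing_mm[axis]
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n", kind,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              paste(format(x$origin_mm), collapse = ", ")))
  rng <- range(x$values)
  cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Read a volume from a NIfTI-1 file
#'
#' Spacing is taken from the header `pixdim`; the origin from the stored
#' transform's translation. Only axis-aligned volumes written by this
#' package (or with a diagonal sform/qform) are geometrically faithful.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"image"`, `"suv"` or `"mask"` — selects the returned class
#'   and its validation.
#' @return An `image_volume`, `suv_map` or `bone_mask`.
#' @export
read_volume <- function(path, kind = c("image", "suv", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  vals <- array(as.double(vals), dim(vals))  # drop niftiImage attributes
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L)
    vals <- array(vals, dim(vals)[1:3])
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  # RNifti reports xforms in RAS; our writer stores a positive diagonal,
  # so undo any sign flips on the translation column.
  sgn <- sign(diag(xf[1:3, 1:3, drop = FALSE]))
  sgn[sgn == 0] <- 1
  origin <- origin * sgn
  switch(kind,
         image = image_volume(vals, spacing, origin),
         suv   = suv_map(vals, spacing, origin),
         mask  = bone_mask(vals, spacing, origin))
}

#' Write a volume to a NIfTI-1 file
#'
#' Masks are written as unsigned 8-bit, other volumes as 32-bit float.
#' Spacing and origin are stored in `pixdim` and the sform/qform
#' translation.
#'
#' @param vol an `image_volume` (or subclass).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  vals <- vol$values
  datatype <- if (inherits(vol, "bone_mask")) "uint8" else "float"
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing_mm
  xf[1:3, 4] <- vol$origin_mm
  img <- RNifti::asNifti(vals)
  img <- RNifti::`pixdim<-`(img, vol$spacing_mm)
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
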