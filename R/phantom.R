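#' Declare a synthetic PET/CT phantom
#'
#' A `phantom_spec` describes a pair of co-registered synthetic volumes —
#' an SUV map on a PET grid and a binary skeletal mask on a (possibly
#' finer) CT grid — built from geometric primitives with analytic ground
#' truth: bones are ellipsoids or finite tubes, lesions are spherical SUV
#' plateaus. Both grids cover the same world box, with voxel `[1,1,1]`
#' centered half a voxel inside the corner, so world coordinates in mm
#' address both volumes consistently.
#'
#' Default tissue values emulate an NaF PET study: soft-tissue background
#' SUV 1, healthy skeletal uptake SUV 4 (well below the automated
#' detection threshold of 15), lesion plateaus chosen by the caller either
#' above 15 (auto-detectable) or in the manual range 6-9.
#'
#' @param shape PET lattice dimensions (3 positive integers).
#' @param pet_spacing_mm PET voxel spacing in mm (default 4 mm isotropic).
#' @param ct_spacing_mm CT voxel spacing in mm (default 2 mm isotropic).
#' @param bones list of primitives: `list(type = "ellipsoid", center_mm,
#'   semiaxes_mm)` or `list(type = "tube", from_mm, to_mm, radius_mm)`.
#' @param lesions list of `list(center_mm, radius_mm, suv_plateau)`.
#' @param background_suv soft-tissue background SUV.
#' @param bone_background_suv healthy-bone SUV; warned about if it reaches
#'   the automated threshold 15.
#' @param noise_sd additive Gaussian noise SD (0 = noise free).
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape, pet_spacing_mm = c(4, 4, 4),
                         ct_spacing_mm = c(2, 2, 2), bones = list(),
                         lesions = list(), background_suv = 1,
                         bone_background_suv = 4, noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(pet_spacing_mm) == 3L, all(pet_spacing_mm > 0),
            length(ct_spacing_mm) == 3L, all(ct_spacing_mm > 0),
            background_suv >= 0, bone_background_suv >= 0, noise_sd >= 0)
  for (b in bones) {
    if (!b$type %in% c("ellipsoid", "tube"))
      stop("unknown bone primitive type: ", b$type, call. = FALSE)
    if (b$type == "ellipsoid" && any(b$semiaxes_mm <= 0))
      stop("ellipsoid semi-axes must be positive", call. = FALSE)
    if (b$type == "tube" && b$radius_mm <= 0)
      stop("tube radius must be positive", call. = FALSE)
  }
  for (l in lesions)
    if (l$radius_mm <= 0) stop("lesion radius must be positive", call. = FALSE)
  if (bone_background_suv >= 15)
    warning("bone background SUV ", bone_background_suv,
            " reaches the automated detection threshold 15; ",
            "the whole skeleton will be detected as one hotspot")
  structure(list(shape = shape, pet_spacing_mm = as.numeric(pet_spacing_mm),
                 ct_spacing_mm = as.numeric(ct_spacing_mm), bones = bones,
                 lesions = lesions, background_suv = background_suv,
                 bone_background_suv = bone_background_suv,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_extent <- function(spec) spec$shape * spec$pet_spacing_mm

phantom_pet_grid <- function(spec) {
  list(dim = spec$shape, spacing_mm = spec$pet_spacing_mm,
       origin_mm = spec$pet_spacing_mm / 2)
}

phantom_ct_grid <- function(spec) {
  ext <- phantom_extent(spec)
  dims <- pmax(1L, as.integer(round(ext / spec$ct_spacing_mm)))
  list(dim = dims, spacing_mm = spec$ct_spacing_mm,
       origin_mm = spec$ct_spacing_mm / 2)
}

# N x 3 matrix of all voxel-center world coordinates of a grid.
grid_points <- function(grid) {
  x <- axis_world(grid, 1); y <- axis_world(grid, 2); z <- axis_world(grid, 3)
  d <- grid$dim
  cbind(rep(x, times = d[2] * d[3]),
        rep(rep(y, each = d[1]), times = d[3]),
        rep(z, each = d[1] * d[2]))
}

in_primitive <- function(pts, prim) {
  if (prim$type == "ellipsoid") {
    c0 <- prim$center_mm; s <- prim$semiaxes_mm
    ((pts[, 1] - c0[1]) / s[1])^2 + ((pts[, 2] - c0[2]) / s[2])^2 +
      ((pts[, 3] - c0[3]) / s[3])^2 <= 1
  } else {  # finite tube (cylinder with flat caps)
    a <- prim$from_mm; b <- prim$to_mm
    ab <- b - a
    L2 <- sum(ab^2)
    dp <- sweep(pts, 2, a)
    t <- (dp %*% ab)[, 1] / L2
    perp2 <- rowSums(dp^2) - t^2 * L2
    t >= 0 & t <= 1 & perp2 <= prim$radius_mm^2
  }
}

in_sphere <- function(pts, center, radius) {
  (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2 <= radius^2
}

primitive_volume_mm3 <- function(prim) {
  if (prim$type == "ellipsoid") {
    4 / 3 * pi * prod(prim$semiaxes_mm)
  } else {
    pi * prim$radius_mm^2 * sqrt(sum((prim$to_mm - prim$from_mm)^2))
  }
}

in_any_bone <- function(pts, bones) {
  inside <- rep(FALSE, nrow(pts))
  for (b in bones) inside <- inside | in_primitive(pts, b)
  inside
}

#' Generate a synthetic phantom with analytic ground truth
#'
#' Renders the `phantom_spec` into an SUV map (PET grid), a bone mask (CT
#' grid) and a `phantom_truth` record. Voxel membership is decided by the
#' voxel *center*; the SUV at a voxel is the maximum of the applicable
#' tissue values (background, bone background, lesion plateaus), plus
#' optional seeded Gaussian noise clipped at zero. Output is
#' deterministic for a fixed spec and seed.
#'
#' @param spec a `phantom_spec`.
#' @return A list with `suv` (`suv_map`), `bone` (`bone_mask` on the CT
#'   grid) and `truth` (see [truth_index()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pg <- phantom_pet_grid(spec)
  cg <- phantom_ct_grid(spec)

  cpts <- grid_points(cg)
  bone_vals <- array(as.numeric(in_any_bone(cpts, spec$bones)), cg$dim)
  bone <- bone_mask(bone_vals, cg$spacing_mm, cg$origin_mm)

  ppts <- grid_points(pg)
  vals <- rep(spec$background_suv, nrow(ppts))
  if (length(spec$bones)) {
    inb <- in_any_bone(ppts, spec$bones)
    vals[inb] <- pmax(vals[inb], spec$bone_background_suv)
  }
  for (l in spec$lesions) {
    ins <- in_sphere(ppts, l$center_mm, l$radius_mm)
    vals[ins] <- pmax(vals[ins], l$suv_plateau)
  }
  if (spec$noise_sd > 0) {
    vals <- vals + with_seed(spec$seed,
                             stats::rnorm(length(vals), 0, spec$noise_sd))
    vals[vals < 0] <- 0
  }
  suv <- suv_map(array(vals, pg$dim), pg$spacing_mm, pg$origin_mm)
  truth <- phantom_truth(spec)
  list(suv = suv, bone = bone, truth = truth)
}

phantom_truth <- function(spec) {
  pg <- phantom_pet_grid(spec)
  cg <- phantom_ct_grid(spec)
  ext <- phantom_extent(spec)
  pet_vv <- prod(pg$spacing_mm)
  ct_vv <- prod(cg$spacing_mm)

  cpts <- grid_points(cg)
  bone_dig <- sum(in_any_bone(cpts, spec$bones)) * ct_vv
  bone_ana <- sum(vapply(spec$bones, primitive_volume_mm3, numeric(1)))

  ppts <- grid_points(pg)
  lesion_rows <- lapply(seq_along(spec$lesions), function(i) {
    l <- spec$lesions[[i]]
    inside_lattice <- all(l$center_mm - l$radius_mm >= 0) &&
      all(l$center_mm + l$radius_mm <= ext)
    if (!inside_lattice)
      warning("lesion ", i, " extends outside the lattice; ",
              "digitized volume used in the analytic truth")
    dig <- sum(in_sphere(ppts, l$center_mm, l$radius_mm)) * pet_vv
    cen <- matrix(l$center_mm, 1, 3)
    data.frame(lesion = i,
               volume_analytic_mm3 = if (inside_lattice)
                 4 / 3 * pi * l$radius_mm^3 else dig,
               volume_digitized_mm3 = dig,
               in_bone = length(spec$bones) > 0 &&
                 any(in_any_bone(cen, spec$bones)),
               suv_plateau = l$suv_plateau)
  })
  lesions <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else
    data.frame(lesion = integer(), volume_analytic_mm3 = numeric(),
               volume_digitized_mm3 = numeric(), in_bone = logical(),
               suv_plateau = numeric())
  structure(list(lesions = lesions, bone_volume_analytic_mm3 = bone_ana,
                 bone_volume_digitized_mm3 = bone_dig),
            class = "phantom_truth")
}

#' Ground-truth index of a phantom
#'
#' The index the pipeline should report for a phantom, recomputable from
#' the spec alone: `100 * skeletal_fraction * sum(in-bone lesion volumes)
#' / bone volume`. With `digitized = TRUE` both numerator and denominator
#' use voxel-center counts on the phantom's own grids (what an ideal
#' pipeline measures); otherwise closed-form sphere / primitive volumes.
#'
#' @param spec a `phantom_spec`.
#' @param skeletal_fraction see [compute_index()].
#' @param digitized use voxel-counted volumes instead of closed forms.
#' @return Expected index in percent.
#' @export
truth_index <- function(spec, skeletal_fraction = 0.33, digitized = FALSE) {
  tr <- suppressWarnings(phantom_truth(spec))
  les <- tr$lesions[tr$lesions$in_bone, , drop = FALSE]
  num <- if (digitized) sum(les$volume_digitized_mm3) else
    sum(les$volume_analytic_mm3)
  den <- if (digitized) tr$bone_volume_digitized_mm3 else
    tr$bone_volume_analytic_mm3
  if (den <= 0) stop("phantom has no bone volume", call. = FALSE)
  100 * skeletal_fraction * num / den
}

#' Read / write a phantom spec as JSON
#' @param path JSON path.
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  num3 <- function(x) as.numeric(unlist(x))
  bones <- lapply(obj$bones, function(b) {
    b$type <- as.character(b$type)
    for (f in c("center_mm", "semiaxes_mm", "from_mm", "to_mm"))
      if (!is.null(b[[f]])) b[[f]] <- num3(b[[f]])
    if (!is.null(b$radius_mm)) b$radius_mm <- as.numeric(b$radius_mm)
    b
  })
  lesions <- lapply(obj$lesions, function(l) {
    l$center_mm <- num3(l$center_mm)
    l$radius_mm <- as.numeric(l$radius_mm)
    l$suv_plateau <- as.numeric(l$suv_plateau)
    l
  })
  phantom_spec(shape = num3(obj$shape),
               pet_spacing_mm = if (is.null(obj$pet_spacing_mm)) c(4, 4, 4)
                 else num3(obj$pet_spacing_mm),
               ct_spacing_mm = if (is.null(obj$ct_spacing_mm)) c(2, 2, 2)
                 else num3(obj$ct_spacing_mm),
               bones = bones, lesions = lesions,
               background_suv = obj$background_suv %||% 1,
               bone_background_suv = obj$bone_background_suv %||% 4,
               noise_sd = obj$noise_sd %||% 0, seed = obj$seed %||% 1L)
}

#' @rdname read_phantom_spec
#' @param spec a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
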