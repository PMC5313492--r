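make_two_sphere_set <- function() {
  spacing <- c(2, 2, 2)
  v <- make_sphere_scene(c(24L, 24L, 24L), spacing,
                         list(list(center = c(12, 12, 12), radius = 5,
                                   value = 20),
                              list(center = c(36, 36, 36), radius = 5,
                                   value = 20)))
  detect_hotspots(v, 15)
}

test_that("bone-overlap filter keeps, trims or removes hotspots correctly", {
  hs <- make_two_sphere_set()
  grid <- hs$grid
  # bone covering only the first sphere entirely
  bone_vals <- array(0, grid$dim)
  bone_vals[1:12, 1:12, 1:12] <- 1
  bone <- bone_mask(bone_vals, grid$spacing_mm, grid$origin_mm)

  kept <- filter_by_bone_overlap(hs, bone)
  expect_equal(n_hotspots(kept), 1L)
  expect_equal(kept$table$hotspot_id, 1L)  # id preserved
  expect_true(kept$table$overlaps_bone)
  expect_equal(kept$table$volume_mm3, hs$table$volume_mm3[1])  # full volume

  # single-voxel overlap: kept with full volume by default,
  # intersection-mode volume equals the explicit voxel-set intersection
  one_vox <- array(0, grid$dim)
  one_vox[hs$voxels[[2]][1]] <- 1
  bone1 <- bone_mask(one_vox, grid$spacing_mm, grid$origin_mm)
  kept1 <- filter_by_bone_overlap(hs, bone1)
  expect_equal(kept1$table$hotspot_id, 2L)
  expect_equal(kept1$table$volume_mm3, hs$table$volume_mm3[2])
  kept1i <- filter_by_bone_overlap(hs, bone1, volume_mode = "intersection")
  n_int <- length(intersect(hs$voxels[[2]], which(one_vox == 1)))
  expect_equal(kept1i$table$voxel_count, n_int)
  expect_equal(kept1i$table$volume_mm3, n_int * prod(grid$spacing_mm))

  # zero overlap anywhere: everything removed
  empty <- bone_mask(array(0, grid$dim), grid$spacing_mm, grid$origin_mm)
  expect_equal(n_hotspots(filter_by_bone_overlap(hs, empty)), 0L)

  # grid mismatch is an error
  other <- bone_mask(array(1, grid$dim), grid$spacing_mm + 1, grid$origin_mm)
  expect_error(filter_by_bone_overlap(hs, other), "grid")
})

test_that("classification validates ids and drives inclusion", {
  hs <- make_two_sphere_set()
  expect_error(apply_classification(hs, data.frame(hotspot_id = 9,
                                                   label = "benign")),
               "9")
  expect_error(apply_classification(
    hs, data.frame(hotspot_id = c(1, 1), label = c("benign", "benign"))),
    "duplicate")
  expect_error(apply_classification(hs, data.frame(hotspot_id = 1,
                                                   label = "odd")),
               "metastasis")

  all_benign <- apply_classification(
    hs, data.frame(hotspot_id = 1:2, label = c("benign", "benign")))
  expect_equal(n_hotspots(included_hotspots(all_benign)), 0L)

  mixed <- apply_classification(
    hs, data.frame(hotspot_id = 1:2, label = c("metastasis", "benign")))
  inc <- included_hotspots(mixed)
  expect_equal(inc$table$hotspot_id, 1L)

  # unlabeled hotspots default to metastasis with a warning; strict errors
  expect_warning(part <- apply_classification(
    hs, data.frame(hotspot_id = 1, label = "benign")), "unlabeled")
  expect_equal(included_hotspots(part)$table$hotspot_id, 2L)
  expect_error(apply_classification(hs,
                                    data.frame(hotspot_id = 1,
                                               label = "benign"),
                                    unlabeled = "strict"), "strict")
})

test_that("three labeled hotspots include exactly the metastasis volumes", {
  spacing <- c(2, 2, 2)
  v <- make_sphere_scene(c(30L, 30L, 30L), spacing,
                         list(list(center = c(12, 12, 12), radius = 5,
                                   value = 20),
                              list(center = c(40, 40, 12), radius = 4,
                                   value = 20),
                              list(center = c(46, 46, 46), radius = 6,
                                   value = 20)))
  hs <- detect_hotspots(v, 15)
  expect_equal(n_hotspots(hs), 3L)
  lab <- apply_classification(
    hs, data.frame(hotspot_id = 1:3,
                   label = c("metastasis", "benign", "metastasis")))
  inc <- included_hotspots(lab)
  expect_equal(sum(inc$table$volume_mm3),
               hs$table$volume_mm3[1] + hs$table$volume_mm3[3])
})

test_that("index arithmetic follows the stated formula exactly", {
  hs <- make_two_sphere_set()
  empty <- subset_set <- included_hotspots(
    apply_classification(hs, data.frame(hotspot_id = 1:2,
                                        label = c("benign", "benign"))))
  expect_equal(compute_index(empty, 1000)$index_percent, 0)

  # sum v = 1000 mm^3, V_bone = 330000 mm^3, fraction 0.33 -> 0.1%
  fake <- hs
  fake$table <- fake$table[1, , drop = FALSE]
  fake$voxels <- fake$voxels[1]
  fake$table$volume_mm3 <- 1000
  r <- compute_index(fake, 330000)
  expect_equal(r$index_percent, 0.1)
  # invariant: recomputable from the result's own fields
  expect_identical(r$index_percent,
                   100 * r$skeletal_fraction * r$total_hotspot_volume_mm3 /
                     r$bone_volume_mm3)

  # hotspot volume equal to bone volume -> 33%
  r33 <- compute_index(fake, 1000)
  expect_equal(r33$index_percent, 33)

  # scale equivariance in the skeletal fraction
  r2 <- compute_index(fake, 330000, skeletal_fraction = 0.66)
  expect_equal(r2$index_percent, 2 * r$index_percent)

  expect_error(compute_index(fake, 0), "positive")
  expect_error(compute_index(fake, -5), "positive")
  expect_error(compute_index(fake, 1000, skeletal_fraction = 0), "0, 1")
})
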