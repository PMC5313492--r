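tube_spec <- function(...) {
  phantom_spec(shape = c(32L, 32L, 32L),
               bones = list(list(type = "tube", from_mm = c(64, 64, 16),
                                 to_mm = c(64, 64, 112), radius_mm = 20)),
               ...)
}

test_that("phantom generation is deterministic and spec-validated", {
  spec <- tube_spec(lesions = list(list(center_mm = c(64, 64, 48),
                                        radius_mm = 8, suv_plateau = 20)),
                    noise_sd = 0.2, seed = 5L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$suv$values, b$suv$values)
  expect_identical(a$bone$values, b$bone$values)

  spec2 <- spec
  spec2$seed <- 6L
  c2 <- generate_phantom(spec2)
  expect_false(identical(a$suv$values, c2$suv$values))

  # noise-free phantoms ignore the seed entirely
  nf1 <- generate_phantom(tube_spec(seed = 1L))
  nf2 <- generate_phantom(tube_spec(seed = 99L))
  expect_identical(nf1$suv$values, nf2$suv$values)

  expect_error(phantom_spec(c(8, 8, 8), bones = list(
    list(type = "cone", center_mm = c(1, 1, 1)))), "primitive")
  expect_error(tube_spec(lesions = list(list(center_mm = c(4, 4, 4),
                                             radius_mm = -1,
                                             suv_plateau = 20))),
               "radius")
  expect_warning(tube_spec(bone_background_suv = 16), "threshold 15")
})

test_that("a lesion-free phantom has truth 0 and SUV max at bone level", {
  ph <- generate_phantom(tube_spec())
  expect_equal(max(ph$suv$values), 4)  # bone background
  expect_equal(min(ph$suv$values), 1)  # soft-tissue background
  expect_equal(truth_index(tube_spec()), 0)
})

test_that("truth_index reproduces closed-form arithmetic", {
  # one r = 6 mm in-bone lesion against a 300000 mm^3 analytic bone volume:
  # tube of radius 20 and length L has volume pi*400*L = 300000
  L <- 300000 / (pi * 400)
  spec <- phantom_spec(shape = c(32L, 32L, 64L),
                       bones = list(list(type = "tube",
                                         from_mm = c(64, 64, 10),
                                         to_mm = c(64, 64, 10 + L),
                                         radius_mm = 20)),
                       lesions = list(list(center_mm = c(64, 64, 60),
                                           radius_mm = 6,
                                           suv_plateau = 20)))
  expect_equal(truth_index(spec), 100 * 0.33 * (4 / 3 * pi * 6^3) / 300000,
               tolerance = 1e-12)
  expect_equal(truth_index(spec), 0.0995, tolerance = 1e-3)
})

test_that("pipeline index matches digitized truth exactly, analytic within 5%", {
  spec <- tube_spec(lesions = list(
    list(center_mm = c(64, 64, 40), radius_mm = 12, suv_plateau = 20),
    list(center_mm = c(64, 64, 90), radius_mm = 14, suv_plateau = 20)))
  ph <- generate_phantom(spec)
  res <- run_pipeline(ph$suv, ph$bone, mode = "auto", sigma_mm = 0)
  dig <- truth_index(spec, digitized = TRUE)
  ana <- truth_index(spec)
  expect_equal(res$index$index_percent, dig, tolerance = 1e-12)
  expect_lt(abs(res$index$index_percent - ana) / ana, 0.05)
})

test_that("digitized truth converges to the analytic truth under refinement", {
  mk <- function(pet_sp, shape) {
    phantom_spec(shape = shape, pet_spacing_mm = rep(pet_sp, 3),
                 ct_spacing_mm = rep(pet_sp / 2, 3),
                 bones = list(list(type = "tube", from_mm = c(64, 64, 16),
                                   to_mm = c(64, 64, 112),
                                   radius_mm = 20)),
                 lesions = list(list(center_mm = c(64, 64, 48),
                                     radius_mm = 10, suv_plateau = 20)))
  }
  ana <- truth_index(mk(4, c(32L, 32L, 32L)))
  err <- vapply(list(mk(4, c(32L, 32L, 32L)), mk(2, c(64L, 64L, 64L))),
                function(s) abs(truth_index(s, digitized = TRUE) - ana) / ana,
                numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("a lesion sticking out of the lattice falls back to voxel counting", {
  spec <- tube_spec(lesions = list(list(center_mm = c(4, 64, 64),
                                        radius_mm = 10, suv_plateau = 20)))
  expect_warning(tr <- pettbi:::phantom_truth(spec), "outside the lattice")
  expect_equal(tr$lesions$volume_analytic_mm3, tr$lesions$volume_digitized_mm3)
})

test_that("phantom spec JSON round-trips through the readers", {
  spec <- tube_spec(lesions = list(list(center_mm = c(64, 64, 48),
                                        radius_mm = 8, suv_plateau = 20)),
                    noise_sd = 0.1, seed = 3L)
  f <- tempfile(fileext = ".json")
  write_phantom_spec(spec, f)
  spec2 <- read_phantom_spec(f)
  expect_equal(spec2$shape, spec$shape)
  expect_equal(spec2$bones, spec$bones)
  expect_equal(spec2$lesions, spec$lesions)
  expect_identical(generate_phantom(spec2)$suv$values,
                   generate_phantom(spec)$suv$values)
})
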