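test_that("phantom generation is deterministic and seed-sensitive", {
  cfg <- small_phantom_config()
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$volume$intensities, p2$volume$intensities)
  expect_identical(p1$truth$depths, p2$truth$depths)
  cfg2 <- small_phantom_config(seed = 2L)
  p3 <- generate_phantom(cfg2)
  expect_false(identical(p1$volume$intensities, p3$volume$intensities))
})

test_that("noise-free phantom voxels equal their layer reflectivity", {
  cfg <- small_phantom_config(speckle_sigma = 0)
  ph <- generate_phantom(cfg)
  vals <- sort(unique(as.vector(ph$volume$intensities)))
  allowed <- sort(unique(c(cfg$vitreous_reflectivity, cfg$layer_reflectivity,
                           cfg$subrpe_reflectivity)))
  expect_equal(vals, allowed)
  # spot-check a voxel in the middle of the ONL at the periphery
  d <- ph$truth$depths
  y_mid <- round((d[1, 1, 6] + d[1, 1, 7]) / 2)
  expect_equal(ph$volume$intensities[1, y_mid + 1, 1],
               cfg$layer_reflectivity[6])
})

test_that("ground-truth surfaces satisfy ordering and reproduce thickness", {
  cfg <- small_phantom_config(speckle_sigma = 0)
  ph <- generate_phantom(cfg)
  d <- ph$truth$depths
  expect_true(all(d[, , 2:12] - d[, , 1:11] >= 0))

  maps <- compute_thickness_maps(ph$truth, axial_spacing_um = cfg$spacing_um[2])
  # construction consistency: maps reproduce the configured thickness field
  # (nominal thicknesses minus the pit profile) to numerical precision
  field <- retidiff:::phantom_thickness_field(cfg)
  expect_lt(max(abs(maps$per_layer - field)), 1e-9)
  # pit center: inner layers thinner by the configured pit depth in total
  ctr <- c((cfg$shape[1] + 1) %/% 2, (cfg$shape[3] + 1) %/% 2)
  pit_loss <- sum(cfg$layer_thickness_um[1:4]) -
    sum(maps$per_layer[ctr[1], ctr[2], 1:4])
  expect_gt(pit_loss, 0.8 * cfg$pit_depth_um)
  # untouched layers keep their thickness at the center too
  expect_equal(as.numeric(maps$per_layer[ctr[1], ctr[2], 5:11]),
               cfg$layer_thickness_um[5:11], tolerance = 1e-9)
})

test_that("OS phantoms are x-mirrored images of their OD twins", {
  cfg_od <- small_phantom_config(speckle_sigma = 0)
  cfg_os <- small_phantom_config(speckle_sigma = 0, eye_side = "OS")
  pod <- generate_phantom(cfg_od)
  pos <- generate_phantom(cfg_os)
  nx <- cfg_od$shape[1]
  expect_identical(pos$volume$intensities,
                   pod$volume$intensities[nx:1, , , drop = FALSE])
  expect_identical(pos$truth$depths, pod$truth$depths[nx:1, , , drop = FALSE])
})

test_that("phantom config validation and axial overflow", {
  expect_error(phantom_config(layer_thickness_um = rep(10, 10)), "11")
  expect_error(phantom_config(layer_reflectivity = rep(2, 11)))
  expect_error(generate_phantom(
    small_phantom_config(layer_thickness_um = rep(60, 11))), "axial")
})

test_that("cohorts carry the programmed effects into the ground truth", {
  co <- generate_cohort(cohort_config(n_subjects = 8L, seed = 3L),
                        small_phantom_config())
  expect_equal(nrow(co$manifest), 8L)
  expect_setequal(unique(co$manifest$eye_side), c("OD", "OS"))

  # zero effects -> identical total thickness for every subject
  z <- cohort_config(n_subjects = 5L, age_slope_um_per_year = 0,
                     sex_offset_um = 0, between_subject_sd_um = 0)
  coz <- generate_cohort(z, small_phantom_config())
  expect_equal(var(coz$manifest$total_thickness_um), 0, tolerance = 1e-18)

  # strong negative effects get clipped with a warning
  big <- cohort_config(n_subjects = 6L, age_slope_um_per_year = 0,
                       sex_offset_um = -400, between_subject_sd_um = 0,
                       seed = 2L)
  expect_warning(generate_cohort(big, small_phantom_config()), "clipped")
})
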