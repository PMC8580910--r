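test_that("degenerate ranges pin every drawn parameter", {
  ph <- coarse_phantom(seed = 5, shape = c(32L, 32L, 32L), spacing = 6)
  spec <- simulation_spec(volume_range = c(3000, 3000), ratio_range = c(1.5, 1.5),
                          angle_range = c(0.7, 0.7), sigma_range = c(1, 1),
                          shift_range = c(5, 5), frequency = 4L)
  set.seed(2)
  p <- sample_params(spec, ph$parcellation)
  expect_equal(p$volume, 3000)
  expect_equal(p$ratio, 1.5)
  expect_equal(p$angles, c(0.7, 0.7, 0.7))
  expect_equal(p$sigma, c(1, 1, 1))
  expect_equal(p$shift, c(5, 5, 5))
  expect_identical(p$frequency, 4L)
  expect_true(p$hemisphere %in% c("left", "right"))
  gm <- gray_matter_mask(ph$parcellation, p$hemisphere)
  idx <- p$seed_voxel + 1L
  expect_identical(gm$values[idx[1], idx[2], idx[3]], 1L)

  set.seed(77); a <- sample_params(spec, ph$parcellation)
  set.seed(77); b <- sample_params(spec, ph$parcellation)
  expect_identical(unclass(a)[names(a) != "seed_voxel"],
                   unclass(b)[names(b) != "seed_voxel"])
  expect_identical(as.integer(a$seed_voxel), as.integer(b$seed_voxel))
})

test_that("volume draws are uniform over the configured range", {
  ph <- coarse_phantom(seed = 5, shape = c(32L, 32L, 32L), spacing = 6)
  spec <- simulation_spec(volume_range = c(500, 5000))
  set.seed(8)
  vols <- replicate(1000, sample_params(spec, ph$parcellation)$volume)
  expect_true(all(vols >= 500 & vols <= 5000))
  # uniform mean 2750, sd 4500/sqrt(12); 3-sigma band for the sample mean
  expect_lt(abs(mean(vols) - 2750), 3 * 4500 / sqrt(12) / sqrt(1000))
})

test_that("simulated cavities stay inside the resectable hemisphere", {
  ph <- coarse_phantom(seed = 9)
  spec <- simulation_spec(volume_range = c(5000, 30000), seed = 421)
  res <- simulate_resection(ph$image, ph$parcellation, spec)
  M_R <- resectable_mask(ph$parcellation, res$params$hemisphere,
                         spec$smooth_radius)
  expect_equal(sum(res$Y_sim$values * (1L - M_R$values)), 0L)
  expect_gt(sum(res$Y_sim$values), 0L)
  # never in the contralateral hemisphere's label set
  contra_labels <- if (res$params$hemisphere == "left")
    ph$label_table$hemisphere_right else ph$label_table$hemisphere_left
  contra <- ph$parcellation$values %in% contra_labels
  expect_equal(sum(res$Y_sim$values[contra]), 0L)
})

test_that("tissue is untouched wherever the alpha channel is zero", {
  ph <- coarse_phantom(seed = 12)
  res <- simulate_resection(ph$image, ph$parcellation,
                            simulation_spec(seed = 33))
  untouched <- res$alpha$values == 0
  expect_gt(sum(untouched), 0)
  expect_identical(res$X_sim$values[untouched], ph$image$values[untouched])
  # the label is exactly the voxelized shape clipped by the resectable mask,
  # so intersection can only shrink it
  spec <- simulation_spec(seed = 33)
  mesh <- cavity_mesh_from_params(res$params, spec)
  M_Sa <- voxelize(translate_to_seed(mesh, attr(res$params$seed_voxel, "mm")),
                   ph$image$grid)
  M_R <- resectable_mask(ph$parcellation, res$params$hemisphere,
                         spec$smooth_radius)
  expect_identical(res$Y_sim$values, M_Sa$values * M_R$values)
  expect_lte(sum(res$Y_sim$values), sum(M_Sa$values))
})

test_that("the simulation is bit-reproducible under a master seed", {
  ph <- coarse_phantom(seed = 14)
  spec <- simulation_spec(seed = 2024)
  r1 <- simulate_resection(ph$image, ph$parcellation, spec)
  r2 <- simulate_resection(ph$image, ph$parcellation, spec)
  expect_identical(r1$X_sim$values, r2$X_sim$values)
  expect_identical(r1$Y_sim$values, r2$Y_sim$values)
  expect_identical(unclass(r1$params)[c("volume", "ratio", "angles", "shift")],
                   unclass(r2$params)[c("volume", "ratio", "angles", "shift")])
})

test_that("cuboid cavities are axis-aligned boxes clipped by the mask", {
  ph <- coarse_phantom(seed = 20)
  spec <- simulation_spec(shape = "cuboid", volume_range = c(20000, 20000),
                          ratio_range = c(2, 2), seed = 7)
  res <- simulate_resection(ph$image, ph$parcellation, spec)
  pos <- which(res$Y_sim$values == 1L, arr.ind = TRUE)
  expect_gt(nrow(pos), 0)
  # the unclipped voxelization of an axis-aligned box is a full lattice box;
  # Y_sim must be its intersection with the resectable mask
  M_R <- resectable_mask(ph$parcellation, res$params$hemisphere,
                         spec$smooth_radius)
  box_mesh <- shape_transform(geodesic_sphere(1),
                              shape_params("cuboid", volume = 20000, ratio = 2))
  centre_mm <- attr(res$params$seed_voxel, "mm")
  box <- voxelize(translate_to_seed(box_mesh, centre_mm), ph$image$grid)
  expect_identical(res$Y_sim$values, box$values * M_R$values)
})

test_that("exhausted retries raise a degenerate-cavity error", {
  ph <- coarse_phantom(seed = 25, shape = c(32L, 32L, 32L), spacing = 6)
  spec <- simulation_spec(volume_range = c(1, 1), frequency = 2L,
                          min_cavity_voxels = 10000L, max_retries = 2L,
                          seed = 5)
  expect_error(simulate_resection(ph$image, ph$parcellation, spec),
               class = "resectr_degenerate_cavity")
})
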