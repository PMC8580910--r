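test_that("geodesic spheres have the closed-form vertex and face counts", {
  for (f in 1:6) {
    m <- geodesic_sphere(f)
    expect_identical(nrow(m$vertices), 10L * f * f + 2L)
    expect_identical(nrow(m$faces), 20L * f * f)
    expect_true(mesh_is_watertight(m))
    expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 1e-9)
  }
  expect_error(geodesic_sphere(0), class = "resectr_bad_frequency")
})

test_that("radial perturbation displaces along the vertex direction only", {
  m <- geodesic_sphere(3)
  expect_equal(perturb_radially(m, function(v) rep(0, nrow(v)))$vertices,
               m$vertices)
  up <- perturb_radially(m, function(v) rep(0.25, nrow(v)))
  expect_equal(sqrt(rowSums(up$vertices^2)), rep(1.25, nrow(m$vertices)),
               tolerance = 1e-12)

  field <- noise_field(5)
  params <- fractal_params(octaves = 4, persistence = 0.5, scale = 0.5,
                           shift = c(3, 1, -2))
  pm <- perturb_radially(m, field, params)
  cross_norm <- sqrt(rowSums(cbind(
    m$vertices[, 2] * pm$vertices[, 3] - m$vertices[, 3] * pm$vertices[, 2],
    m$vertices[, 3] * pm$vertices[, 1] - m$vertices[, 1] * pm$vertices[, 3],
    m$vertices[, 1] * pm$vertices[, 2] - m$vertices[, 2] * pm$vertices[, 1])^2))
  expect_lt(max(cross_norm), 1e-12)
  expect_identical(pm$faces, m$faces)

  degenerate <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                              matrix(c(1, 2, 3), 1))
  expect_error(perturb_radially(degenerate, function(v) rep(0, 3)),
               class = "resectr_degenerate_vertex")
})

test_that("semiaxes follow the two formula modes and cancel the ratio", {
  expect_equal(semiaxes(4 * pi / 3, 1, "volume-exact"), c(1, 1, 1))
  expect_equal(semiaxes(4 / 3, 1, "paper-literal"), c(1, 1, 1))
  for (v in c(500, 10000, 50000)) {
    r <- semiaxes(v, 2, "volume-exact")
    expect_equal(4 / 3 * pi * prod(r), v, tolerance = 1e-9) # lambda cancels
    expect_equal(r[2] / r[1], 2)
    expect_equal(r[1] / r[3], 2)
  }
  expect_error(semiaxes(-1, 1), class = "resectr_bad_volume")
  expect_error(semiaxes(10, 0.5), class = "resectr_bad_volume")
})

test_that("shape transforms scale, rotate, and box the mesh as configured", {
  m <- geodesic_sphere(4)
  iso <- shape_transform(m, shape_params("ellipsoid", volume = 4 * pi / 3 * 27,
                                         ratio = 1))
  expect_equal(sqrt(rowSums(iso$vertices^2)), rep(3, nrow(m$vertices)),
               tolerance = 1e-9)

  # rotation preserves enclosed volume and watertightness
  rot <- shape_transform(m, shape_params("ellipsoid", volume = 1000, ratio = 1.5,
                                         angles = c(0.4, -1.1, 2.2)))
  norot <- shape_transform(m, shape_params("ellipsoid", volume = 1000,
                                           ratio = 1.5))
  expect_true(mesh_is_watertight(rot))
  expect_equal(mesh_volume(rot), mesh_volume(norot), tolerance = 1e-9)

  m8 <- geodesic_sphere(8)
  for (v in c(1000, 10000)) {
    e <- shape_transform(m8, shape_params("ellipsoid", volume = v, ratio = 1.7))
    expect_lt(abs(mesh_volume(e) - v) / v, 0.01)
  }

  r <- semiaxes(2000, 2)
  box <- shape_transform(m, shape_params("cuboid", volume = 2000, ratio = 2,
                                         angles = c(1, 1, 1)))
  expect_identical(nrow(box$faces), 12L)
  expect_true(mesh_is_watertight(box))
  expect_equal(mesh_volume(box), 8 * prod(r), tolerance = 1e-9)
  expect_equal(apply(box$vertices, 2, max), r, tolerance = 1e-12)
})

test_that("translation is exact and invertible", {
  m <- geodesic_sphere(2)
  expect_equal(translate_to_seed(m, c(0, 0, 0))$vertices, m$vertices)
  a <- c(10, -5, 3)
  t1 <- translate_to_seed(m, a)
  expect_equal(colMeans(t1$vertices) - colMeans(m$vertices), a,
               tolerance = 1e-12, ignore_attr = TRUE)
  back <- translate_to_seed(t1, -a)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-12)
})

test_that("voxelization matches analytic volume and handles empty overlap", {
  g <- image_grid(c(24, 24, 24), local({
    a <- diag(4); a[1:3, 4] <- -11.5; a
  }))
  ball <- shape_transform(geodesic_sphere(6),
                          shape_params("ellipsoid", volume = 4 / 3 * pi * 1000))
  mask <- voxelize(ball, g)
  expect_lt(abs(sum(mask$values) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)

  far <- translate_to_seed(ball, c(1000, 0, 0))
  expect_equal(sum(voxelize(far, g)$values), 0L)

  open_mesh <- triangle_mesh(geodesic_sphere(1)$vertices,
                             geodesic_sphere(1)$faces[-1, ])
  expect_error(voxelize(open_mesh, g), class = "resectr_open_mesh")
})

test_that("parity voxelization agrees with the winding-number oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(16:32, 1)
    a <- diag(4)
    a[1:3, 4] <- -(n - 1) / 2
    g <- image_grid(c(n, n, n), a)
    mesh <- random_test_mesh(extent = n)
    got <- voxelize(mesh, g)$values
    want <- winding_voxelize(mesh, g)
    expect_identical(got, want)
  }
})
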