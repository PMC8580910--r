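# A 2x2x2 toy parcellation: one voxel each of left GM, right GM, brainstem,
# and background elsewhere.
toy_parcellation <- function() {
  g <- image_grid(c(2, 2, 2))
  lab <- array(0L, c(2, 2, 2))
  lab[1, 1, 1] <- 1L # left GM
  lab[2, 1, 1] <- 2L # right GM
  lab[1, 2, 1] <- 7L # brainstem
  lab[2, 2, 2] <- 5L # left ventricle
  label_volume(lab, g, phantom_label_table())
}

test_that("label tables validate roles and survive a text round trip", {
  tab <- phantom_label_table()
  expect_error(label_table(background = 0, brainstem = 7, cerebellum = 8,
                           gm_left = 1, gm_right = 2,
                           hemisphere_left = c(1, 3), hemisphere_right = c(1, 4),
                           ventricles = 5),
               class = "resectr_bad_label_table")
  expect_error(label_table(background = 0, brainstem = integer(0),
                           cerebellum = 8, gm_left = 1, gm_right = 2,
                           hemisphere_left = 1, hemisphere_right = 2,
                           ventricles = 5),
               class = "resectr_role_missing")
  path <- withr::local_tempfile(fileext = ".txt")
  write_label_table(tab, path)
  expect_identical(unclass(read_label_table(path)), unclass(tab))
})

test_that("hemisphere choice is fair, seeded, and has a complement", {
  set.seed(10); h1 <- choose_hemisphere()
  set.seed(10); h2 <- choose_hemisphere()
  expect_identical(h1, h2)
  set.seed(123)
  draws <- replicate(10000, choose_hemisphere())
  expect_gt(mean(draws == "left"), 0.48)
  expect_lt(mean(draws == "left"), 0.52)
  expect_identical(other_hemisphere("left"), "right")
  expect_identical(other_hemisphere("right"), "left")
})

test_that("gray matter masks select exactly the hemisphere's GM labels", {
  P <- toy_parcellation()
  gm <- gray_matter_mask(P, "left")
  expect_identical(which(gm$values == 1L), 1L)
  gmr <- gray_matter_mask(P, "right")
  expect_identical(which(gmr$values == 1L), 2L)

  # parcellation with no GM at all -> error, not an empty mask
  g <- image_grid(c(2, 2, 2))
  noGM <- label_volume(array(0L, c(2, 2, 2)), g, phantom_label_table())
  expect_error(gray_matter_mask(noGM, "left"), class = "resectr_role_missing")

  ph <- coarse_phantom(seed = 4)
  tab <- ph$label_table
  contra <- ph$parcellation$values %in% tab$hemisphere_right
  expect_equal(sum(gray_matter_mask(ph$parcellation, "left")$values[contra]), 0L)
})

test_that("resectable mask applies the exclusion rule before smoothing", {
  P <- toy_parcellation()
  res <- resectable_mask(P, "left", smooth_radius = 0)
  # excluded: background 0, brainstem 7, cerebellum 8, right hemisphere {2,4,6}
  expect_identical(which(res$values == 1L), c(1L, 8L)) # left GM + left ventricle
  expect_true(all(gray_matter_mask(P, "left")$values <= res$values))
})

test_that("morphological smoothing respects convex solids", {
  g <- image_grid(c(30, 30, 30))
  arr <- array(0L, c(30, 30, 30))
  arr[6:25, 6:25, 6:25] <- 1L
  m <- binary_mask(arr, g)
  # closing is the identity on a convex solid
  off <- resectr:::sphere_offsets(3)
  closed <- resectr:::morph(resectr:::morph(m, off, TRUE), off, FALSE)
  expect_identical(closed$values, arr)
  # opening with a spherical element can only round edges and corners:
  # nothing is added, and voxels close to at most one face survive
  sm <- smooth_mask(m, radius = 3)$values
  expect_true(all(sm <= arr))
  idx <- which(arr == 1L, arr.ind = TRUE)
  near_face <- (idx < 6 + 3) + (idx > 25 - 3)
  safe <- rowSums(near_face) <= 1
  expect_true(all(sm[idx[safe, , drop = FALSE]] == 1L))
})

test_that("resectable masks of a symmetric phantom mirror across the midline", {
  ph <- coarse_phantom(seed = 8)
  L <- resectable_mask(ph$parcellation, "left")$values
  R <- resectable_mask(ph$parcellation, "right")$values
  expect_identical(L, R[dim(R)[1]:1, , ])
  # pre-smoothing mask never overlaps the contralateral hemisphere labels
  raw <- resectable_mask(ph$parcellation, "left", smooth_radius = 0)$values
  contra <- ph$parcellation$values %in% ph$label_table$hemisphere_right
  expect_equal(sum(raw[contra]), 0L)
})

test_that("ventricle mask counts the phantom's CSF voxels", {
  ph <- coarse_phantom(seed = 3)
  mv <- ventricle_mask(ph$parcellation)
  expect_identical(sum(mv$values),
                   sum(ph$parcellation$values %in% c(5L, 6L)))
  bg <- ph$parcellation$values == 0L
  expect_equal(sum(mv$values[bg]), 0L)
  g <- image_grid(c(2, 2, 2))
  noV <- label_volume(array(1L, c(2, 2, 2)), g, phantom_label_table())
  expect_error(ventricle_mask(noV), class = "resectr_role_missing")
})

test_that("seed voxels are uniform over the mask and fail when empty", {
  g <- image_grid(c(2, 2, 2))
  one <- array(0L, c(2, 2, 2)); one[2, 1, 2] <- 1L
  expect_identical(as.integer(sample_seed_voxel(binary_mask(one, g))),
                   c(1L, 0L, 1L))
  empty <- binary_mask(array(0L, c(2, 2, 2)), g)
  expect_error(sample_seed_voxel(empty), class = "resectr_empty_mask")

  four <- array(0L, c(2, 2, 2)); four[c(1, 3, 5, 7)] <- 1L
  mask <- binary_mask(four, g)
  set.seed(31)
  draws <- replicate(10000, paste(sample_seed_voxel(mask), collapse = ","))
  freqs <- table(draws) / 10000
  expect_identical(length(freqs), 4L)
  expect_true(all(freqs > 0.22 & freqs < 0.28))
})
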