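mask_of <- function(idx, shape = c(4, 4, 4)) {
  arr <- array(0L, shape)
  arr[idx] <- 1L
  binary_mask(arr, image_grid(shape))
}

test_that("Dice handles identity, disjoint, partial overlap and emptiness", {
  A <- mask_of(1:4)
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, mask_of(5:8)), 0)
  expect_equal(dice(A, mask_of(3:6)), 0.5) # |A|=|B|=4, overlap 2
  expect_equal(dice(A, mask_of(3:6)), dice(mask_of(3:6), A))
  expect_warning(d <- dice(mask_of(integer(0)), mask_of(integer(0))), "empty")
  expect_equal(d, 1)
  g2 <- image_grid(c(5, 5, 5))
  expect_error(dice(A, binary_mask(array(0L, c(5, 5, 5)), g2)),
               class = "resectr_grid_mismatch")
})

test_that("thresholding counts ties as positive", {
  g <- image_grid(c(2, 2, 2))
  v <- scalar_volume(array(c(0.4, 0.5, 0.6, 0.7, 0, 1, 0.49999, 0.5),
                           c(2, 2, 2)), g)
  m <- threshold_prediction(v, 0.5)
  expect_identical(as.vector(m$values), c(0L, 1L, 1L, 1L, 0L, 1L, 0L, 1L))
  expect_identical(sum(threshold_prediction(v, 1.0)$values), 1L)
  all6 <- threshold_prediction(scalar_volume(array(0.6, c(2, 2, 2)), g), 0.5)
  expect_identical(sum(all6$values), 8L)
})

test_that("largest-component filtering keeps exactly the biggest blob", {
  shape <- c(10, 10, 10)
  arr <- array(0L, shape)
  arr[2:4, 2:4, 2] <- 1L      # 9 voxels + 1 diagonal neighbour = 10
  arr[5, 5, 3] <- 1L          # 26-connected to the corner of the block
  arr[8:10, 8, 8] <- 1L       # separate 3-voxel component
  m <- binary_mask(arr, image_grid(shape))
  kept <- keep_largest_component(m)
  expect_identical(sum(kept$values), 10L)
  expect_identical(kept$values[8, 8, 8], 0L)
  expect_identical(kept$values[5, 5, 3], 1L) # diagonal connectivity

  single <- mask_of(1:3)
  expect_identical(keep_largest_component(single)$values, single$values)
  empty <- mask_of(integer(0))
  expect_identical(keep_largest_component(empty)$values, empty$values)
  expect_equal(dice(keep_largest_component(single), single), 1)
})

test_that("Mann-Whitney exact p-values match hand enumeration and wilcox.test", {
  r <- mann_whitney_one_tailed(c(1, 2), c(3, 4), "less")
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 1 / 6) # 1 of C(4,2)=6 rank assignments
  expect_identical(r$method, "exact")

  same <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3), "less")
  expect_gte(same$p.value, 0.5)
  same2 <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_gte(same2$p.value, 0.5)

  set.seed(44)
  for (rep in 1:25) {
    xs <- round(rnorm(sample(3:10, 1)), 6)
    ys <- round(rnorm(sample(3:10, 1)) + runif(1, -1, 1), 6)
    for (alt in c("less", "greater")) {
      ours <- mann_whitney_one_tailed(xs, ys, alt)
      ref <- stats::wilcox.test(xs, ys, alternative = alt, exact = TRUE)
      expect_equal(ours$U, unname(ref$statistic))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_error(mann_whitney_one_tailed(numeric(0), 1, "less"),
               class = "resectr_empty_sample")
})

test_that("exact and approximate Mann-Whitney p agree for moderate samples", {
  set.seed(55)
  for (rep in 1:100) {
    xs <- rnorm(8)
    ys <- rnorm(8, sd = 1.2)
    exact <- mann_whitney_one_tailed(xs, ys, "less")
    # force the approximation by exceeding the exact-enumeration cutoff
    big <- mann_whitney_one_tailed(c(xs, 100 + seq_len(20)),
                                   c(ys, 100 + seq_len(20) + 0.5), "less")
    expect_identical(exact$method, "exact")
    expect_identical(big$method, "normal approximation")
    mu <- 8 * 8 / 2
    sigma <- sqrt(8 * 8 * 17 / 12)
    approx_p <- pnorm((exact$U - mu + 0.5) / sigma)
    expect_lt(abs(exact$p.value - approx_p), 0.02)
  }
})

test_that("the experiment-count correction divides by n(n-1)", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 5), 0.0025)
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 6)
  expect_equal(bonferroni_alpha(0.05, 3, conventional = TRUE), 0.05 / 3)
  expect_error(bonferroni_alpha(0.05, 1), class = "resectr_bad_alpha_level")
  expect_error(bonferroni_alpha(1.5, 3), class = "resectr_bad_alpha_level")
})

test_that("median and IQR use linear-interpolation quantiles", {
  s <- median_iqr(3)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 0)
  s2 <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(s2$median, 3)
  expect_equal(s2$iqr, 2)
  set.seed(3)
  x <- rnorm(37)
  a <- median_iqr(x)
  b <- median_iqr(x + 17.5)
  expect_equal(b$median, a$median + 17.5)
  expect_equal(b$iqr, a$iqr)
  expect_error(median_iqr(numeric(0)), class = "resectr_empty_sample")
})

test_that("segmentation evaluation composes threshold, postprocessing, Dice", {
  g <- image_grid(c(6, 6, 6))
  truth_arr <- array(0L, c(6, 6, 6)); truth_arr[2:4, 2:4, 2:4] <- 1L
  truth <- binary_mask(truth_arr, g)
  probs <- array(0, c(6, 6, 6))
  probs[2:4, 2:4, 2:4] <- 0.9
  probs[6, 6, 6] <- 0.8 # spurious island
  pred <- scalar_volume(probs, g)
  expect_lt(evaluate_segmentation(pred, truth), 1)
  expect_equal(evaluate_segmentation(pred, truth, largest_component = TRUE), 1)
})
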