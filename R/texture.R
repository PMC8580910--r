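#' CSF intensity statistics from the ventricles
#'
#' Mean and population (1/n) standard deviation of the preoperative image
#' intensities inside the ventricle mask; these parameterise the normal
#' model of CSF intensity.
#'
#' @param X_pre A `scalar_volume`.
#' @param M_V A non-empty `binary_mask` on the same grid.
#' @return A `csf_stats` object with fields `mean` and `sd`.
#' @export
csf_statistics <- function(X_pre, M_V) {
  if (!same_grid(X_pre$grid, M_V$grid))
    stop_resectr("image and ventricle mask are on different grids",
                 "resectr_grid_mismatch")
  vals <- X_pre$values[M_V$values == 1L]
  if (length(vals) == 0L)
    stop_resectr("ventricle mask is empty", "resectr_empty_mask")
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2))
  csf_stats(m, s)
}

#' @rdname csf_statistics
#' @param mean,sd CSF intensity mean and standard deviation (sd >= 0).
#' @export
csf_stats <- function(mean, sd) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop_resectr("CSF stats must be finite with sd >= 0", "resectr_bad_stats")
  structure(list(mean = mean, sd = sd), class = "csf_stats")
}

#' Synthesize a CSF-like intensity volume
#'
#' Independent draws from N(mean, sd) at every voxel of the grid, using R's
#' global random number stream.
#'
#' @param grid Target `image_grid`.
#' @param stats A [csf_stats()].
#' @return A `scalar_volume`.
#' @export
make_csf_volume <- function(grid, stats) {
  stopifnot(inherits(stats, "csf_stats"))
  n <- prod(grid$shape)
  vals <- if (stats$sd == 0) rep(stats$mean, n)
          else stats::rnorm(n, stats$mean, stats$sd)
  scalar_volume(array(vals, dim = grid$shape), grid)
}

#' Gaussian blur specification for the alpha channel
#' @param sigma Per-axis standard deviations in mm (length 3 or scalar,
#'   each >= 0).
#' @return A `blur_spec`.
#' @export
blur_spec <- function(sigma = c(1, 1, 1)) {
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (!all(is.finite(sigma)) || any(sigma < 0))
    stop_resectr("blur sigma must be >= 0", "resectr_bad_blur")
  structure(list(sigma = sigma), class = "blur_spec")
}

#' Smooth alpha channel from the cavity label
#'
#' Convolves the binary cavity label with a unit-sum truncated Gaussian
#' kernel (sigma in mm, converted to voxels through the grid spacing; zero
#' padding at the boundary), yielding blending weights in [0, 1] that mimic
#' partial-volume effects at the cavity boundary. A zero sigma reproduces
#' the label exactly.
#'
#' @param Y_sim A `binary_mask`.
#' @param blur A [blur_spec()].
#' @param truncate Kernel truncation, in standard deviations.
#' @return A `scalar_volume` with values in [0, 1].
#' @export
alpha_channel <- function(Y_sim, blur = blur_spec(), truncate = 4) {
  stopifnot(inherits(blur, "blur_spec"))
  sigma_vox <- blur$sigma / grid_spacing(Y_sim$grid)
  vals <- gaussian_blur_cpp(as.numeric(Y_sim$values), Y_sim$grid$shape,
                            sigma_vox, truncate)
  vals <- pmin(pmax(vals, 0), 1) # clip float round-off
  scalar_volume(array(vals, dim = Y_sim$grid$shape), Y_sim$grid)
}

#' Alpha-blend the CSF texture into the preoperative image
#'
#' The convex combination X_sim = alpha * X_csf + (1 - alpha) * X_pre,
#' elementwise. Wherever alpha is 0 the preoperative image is returned
#' exactly.
#'
#' @param X_pre,X_csf `scalar_volume`s on a common grid.
#' @param alpha A `scalar_volume` of weights in [0, 1] on the same grid.
#' @return A `scalar_volume`.
#' @export
blend <- function(X_pre, X_csf, alpha) {
  if (!same_grid(X_pre$grid, X_csf$grid) || !same_grid(X_pre$grid, alpha$grid))
    stop_resectr("blend inputs are on different grids", "resectr_grid_mismatch")
  a <- alpha$values
  if (min(a) < 0 || max(a) > 1)
    stop_resectr("alpha values must lie in [0, 1]", "resectr_bad_alpha")
  scalar_volume(a * X_csf$values + (1 - a) * X_pre$values, X_pre$grid)
}
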