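#' Seeded gradient table for 3D simplex noise
#'
#' Builds the 512-entry permutation table (a seeded shuffle of 0..255,
#' doubled) that selects pseudorandom gradients on the simplicial grid. The
#' same seed always yields the same field.
#'
#' @param seed Integer seed for the table shuffle.
#' @return An object of class `noise_field`.
#' @export
noise_field <- function(seed = 0L) {
  perm256 <- with_seed(as.integer(seed), sample.int(256L) - 1L)
  structure(list(perm = c(perm256, perm256), seed = as.integer(seed)),
            class = "noise_field")
}

# Run code under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fractal (multi-octave) noise parameters
#'
#' @param octaves Number of octaves (>= 1).
#' @param persistence Geometric weight decay per octave, in (0, 1].
#' @param scale Smoothness parameter: input points are divided by `scale`
#'   (same units as the points; mm for meshes). Must be positive.
#' @param shift Length-3 offset added to points before scaling; acts as a
#'   continuous random seed.
#' @param lacunarity Per-octave frequency multiplier (>= 1, default 2).
#' @param normalize If TRUE (default) the octave sum is divided by the sum of
#'   weights so values stay within [-1, 1] for any number of octaves.
#' @return An object of class `fractal_params`.
#' @export
fractal_params <- function(octaves = 4L, persistence = 0.5, scale = 1,
                           shift = c(0, 0, 0), lacunarity = 2,
                           normalize = TRUE) {
  octaves <- as.integer(octaves)
  if (is.na(octaves) || octaves < 1L)
    stop_resectr("octaves must be a positive integer", "resectr_bad_noise_params")
  if (!is.finite(persistence) || persistence <= 0 || persistence > 1)
    stop_resectr("persistence must be in (0, 1]", "resectr_bad_noise_params")
  if (!is.finite(scale) || scale <= 0)
    stop_resectr("scale must be positive", "resectr_bad_noise_params")
  if (length(shift) != 3L || !all(is.finite(shift)))
    stop_resectr("shift must be a finite 3-vector", "resectr_bad_noise_params")
  if (!is.finite(lacunarity) || lacunarity < 1)
    stop_resectr("lacunarity must be >= 1", "resectr_bad_noise_params")
  structure(list(octaves = octaves, persistence = persistence, scale = scale,
                 shift = as.numeric(shift), lacunarity = lacunarity,
                 normalize = isTRUE(normalize)),
            class = "fractal_params")
}

as_points <- function(points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  if (ncol(pts) != 3L)
    stop_resectr("points must be 3-vectors", "resectr_bad_point")
  if (!all(is.finite(pts)))
    stop_resectr("points must be finite", "resectr_bad_point")
  storage.mode(pts) <- "double"
  pts
}

#' Single-octave 3D simplex noise
#'
#' Smooth, deterministic noise bounded in [-1, 1], evaluated at one or more
#' points.
#'
#' @param field A [noise_field()].
#' @param points 3-vector or n x 3 matrix of evaluation points.
#' @return Numeric vector of noise values in [-1, 1].
#' @export
simplex3 <- function(field, points) {
  stopifnot(inherits(field, "noise_field"))
  simplex3_cpp(as_points(points), field$perm)
}

#' Multi-octave simplex noise
#'
#' Weighted sum over octaves n = 1..omega of persistence^(n-1) times simplex
#' noise at lacunarity^(n-1) times the point, normalised (by default) by the
#' weight sum so the result remains in [-1, 1].
#'
#' @inheritParams simplex3
#' @param params A [fractal_params()]; its `scale`/`shift` are *not* applied
#'   here (see [vertex_displacement()]), only octave structure.
#' @return Numeric vector of values.
#' @export
fractal_noise <- function(field, points, params) {
  stopifnot(inherits(field, "noise_field"), inherits(params, "fractal_params"))
  fractal3_cpp(as_points(points), field$perm, params$octaves,
               params$persistence, params$lacunarity, params$normalize)
}

#' Noise displacement of mesh vertices
#'
#' The displacement of a vertex v is the fractal noise evaluated at
#' (v + shift) / scale — shifting adds stochasticity (a continuous seed) and
#' the scale controls surface smoothness.
#'
#' @param field A [noise_field()].
#' @param vertices 3-vector or n x 3 matrix of vertex positions.
#' @param params A [fractal_params()].
#' @return Numeric vector of displacements (same units as the vertices).
#' @export
vertex_displacement <- function(field, vertices, params) {
  stopifnot(inherits(params, "fractal_params"))
  pts <- as_points(vertices)
  pts <- sweep(pts, 2, params$shift, "+") / params$scale
  fractal_noise(field, pts, params)
}
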