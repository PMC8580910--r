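#' Simulation specification: parameter ranges for one cavity draw
#'
#' Ranges are inclusive `[min, max]` pairs sampled uniformly; give a
#' degenerate range (both ends equal) to pin a parameter. Defaults are
#' engineering choices (not validated against any trained model) spanning
#' small to lobectomy-scale cavities.
#'
#' @param volume_range Cavity volume range, mm^3.
#' @param ratio_range Semiaxis ratio (lambda) range.
#' @param angle_range Rotation range per axis, radians.
#' @param frequency Geodesic frequency f (integer, fixed).
#' @param octaves,persistence,lacunarity Fractal noise structure.
#' @param zeta Noise smoothness scale in unit-sphere coordinates (the mesh is
#'   perturbed before scaling, so 0.5 means half the sphere radius).
#' @param shift_range Range for each component of the noise shift mu.
#' @param sigma_range Alpha-channel blur sigma range per axis, mm.
#' @param shape One of `"noisy"`, `"ellipsoid"`, `"cuboid"`.
#' @param semiaxes_mode Passed to [semiaxes()].
#' @param smooth_radius Resectable-mask smoothing radius, voxels.
#' @param min_cavity_voxels Redraw the seed voxel while the cavity has fewer
#'   positive voxels than this floor.
#' @param max_retries Seed-voxel redraw limit (>= 1).
#' @param seed Master seed; NULL uses the current RNG state.
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(volume_range = c(500, 50000),
                            ratio_range = c(1, 2),
                            angle_range = c(0, 2 * pi),
                            frequency = 16L,
                            octaves = 4L, persistence = 0.5, lacunarity = 2,
                            zeta = 0.5, shift_range = c(-1000, 1000),
                            sigma_range = c(0.5, 2),
                            shape = c("noisy", "ellipsoid", "cuboid"),
                            semiaxes_mode = c("volume-exact", "paper-literal"),
                            smooth_radius = 3,
                            min_cavity_voxels = 1L,
                            max_retries = 10L,
                            seed = NULL) {
  shape <- match.arg(shape)
  semiaxes_mode <- match.arg(semiaxes_mode)
  rng_ok <- function(r, lo = -Inf) length(r) == 2L && all(is.finite(r)) &&
    r[1] <= r[2] && r[1] >= lo
  if (!rng_ok(volume_range, lo = 1e-9) || !rng_ok(ratio_range, lo = 1) ||
      !rng_ok(angle_range) || !rng_ok(sigma_range, lo = 0) ||
      !rng_ok(shift_range))
    stop_resectr("invalid parameter range", "resectr_bad_spec")
  if (as.integer(max_retries) < 1L)
    stop_resectr("max_retries must be >= 1", "resectr_bad_spec")
  structure(list(volume_range = volume_range, ratio_range = ratio_range,
                 angle_range = angle_range, frequency = as.integer(frequency),
                 octaves = as.integer(octaves), persistence = persistence,
                 lacunarity = lacunarity, zeta = zeta,
                 shift_range = shift_range, sigma_range = sigma_range,
                 shape = shape, semiaxes_mode = semiaxes_mode,
                 smooth_radius = smooth_radius,
                 min_cavity_voxels = as.integer(min_cavity_voxels),
                 max_retries = as.integer(max_retries),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_spec")
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Draw one concrete parameter realization
#'
#' Independent uniform draws within each configured range; the hemisphere is
#' chosen with equal probability and the seed voxel uniformly over the
#' hemisphere's cortical gray matter.
#'
#' @param spec A [simulation_spec()].
#' @param P A `label_volume` with a label table.
#' @return A `drawn_params` object.
#' @export
sample_params <- function(spec, P) {
  stopifnot(inherits(spec, "simulation_spec"))
  h <- choose_hemisphere()
  gm <- gray_matter_mask(P, h)
  a <- sample_seed_voxel(gm)
  structure(list(
    volume = runif1(spec$volume_range),
    ratio = runif1(spec$ratio_range),
    angles = c(runif1(spec$angle_range), runif1(spec$angle_range),
               runif1(spec$angle_range)),
    frequency = spec$frequency,
    octaves = spec$octaves, persistence = spec$persistence,
    lacunarity = spec$lacunarity, zeta = spec$zeta,
    shift = c(runif1(spec$shift_range), runif1(spec$shift_range),
              runif1(spec$shift_range)),
    sigma = c(runif1(spec$sigma_range), runif1(spec$sigma_range),
              runif1(spec$sigma_range)),
    hemisphere = h, seed_voxel = a,
    noise_seed = sample.int(.Machine$integer.max, 1L)),
    class = "drawn_params")
}

#' @export
print.drawn_params <- function(x, ...) {
  cat(sprintf(
    "<drawn_params> %s hemisphere, v = %.0f mm^3, lambda = %.2f, f = %d\n",
    x$hemisphere, x$volume, x$ratio, x$frequency))
  invisible(x)
}

#' Rebuild the cavity mesh for a drawn parameter set
#'
#' Deterministically reconstructs the shaped (but untranslated) cavity
#' surface from a `drawn_params` realization, e.g. to replay or inspect a
#' logged draw.
#'
#' @param params A `drawn_params` from [sample_params()].
#' @param spec The [simulation_spec()] the draw came from.
#' @return A `triangle_mesh` centred at the origin.
#' @export
cavity_mesh_from_params <- function(params, spec) {
  sp <- shape_params(mode = spec$shape, volume = params$volume,
                     ratio = params$ratio,
                     angles = if (spec$shape == "cuboid") c(0, 0, 0) else params$angles,
                     frequency = params$frequency,
                     semiaxes_mode = spec$semiaxes_mode)
  mesh <- geodesic_sphere(params$frequency)
  if (spec$shape == "noisy") {
    fp <- fractal_params(octaves = params$octaves,
                         persistence = params$persistence,
                         scale = params$zeta, shift = params$shift,
                         lacunarity = params$lacunarity)
    mesh <- perturb_radially(mesh, noise_field(params$noise_seed), fp)
  }
  shape_transform(mesh, sp)
}

#' Simulate one resection: preoperative image to (X_sim, Y_sim)
#'
#' Runs the full generative pipeline: build and perturb the cavity surface,
#' rotate/scale it to the drawn volume, centre it on a gray matter seed
#' voxel, voxelize, restrict to the resectable hemisphere mask, then fill
#' the cavity with ventricle-matched CSF texture through a blurred alpha
#' channel. If the cavity has fewer positive voxels than the configured
#' floor, the seed voxel is redrawn up to the retry limit.
#'
#' @param X_pre Preoperative `scalar_volume`.
#' @param P Parcellation `label_volume` (same grid) with a label table.
#' @param spec A [simulation_spec()].
#' @return A `simulation_result`: list with `X_sim`, `Y_sim`, `alpha`,
#'   `params`, and `cavity_volume_mm3`.
#' @export
simulate_resection <- function(X_pre, P, spec = simulation_spec()) {
  if (!same_grid(X_pre$grid, P$grid))
    stop_resectr("image and parcellation are on different grids",
                 "resectr_grid_mismatch")
  if (!is.null(spec$seed)) set.seed(spec$seed)

  params <- sample_params(spec, P)
  M_R <- resectable_mask(P, params$hemisphere, spec$smooth_radius)
  mesh <- cavity_mesh_from_params(params, spec)
  gm <- NULL

  Y <- NULL
  for (attempt in seq_len(spec$max_retries)) {
    placed <- translate_to_seed(mesh, attr(params$seed_voxel, "mm"))
    M_Sa <- voxelize(placed, P$grid)
    Yv <- M_Sa$values * M_R$values
    if (sum(Yv) >= spec$min_cavity_voxels) {
      Y <- binary_mask(Yv, P$grid)
      break
    }
    if (attempt == spec$max_retries)
      stop_resectr("degenerate cavity: retry limit exhausted",
                   "resectr_degenerate_cavity", params = params)
    if (is.null(gm)) gm <- gray_matter_mask(P, params$hemisphere)
    params$seed_voxel <- sample_seed_voxel(gm)
  }

  stats <- csf_statistics(X_pre, ventricle_mask(P))
  X_csf <- make_csf_volume(P$grid, stats)
  alpha <- alpha_channel(Y, blur_spec(params$sigma))
  X_sim <- blend(X_pre, X_csf, alpha)

  voxvol <- prod(grid_spacing(P$grid))
  structure(list(X_sim = X_sim, Y_sim = Y, alpha = alpha, params = params,
                 csf = stats, cavity_volume_mm3 = sum(Y$values) * voxvol),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> cavity %.0f mm^3 (%d voxels), %s hemisphere\n",
    x$cavity_volume_mm3, sum(x$Y_sim$values), x$params$hemisphere))
  invisible(x)
}
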