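#' Synthetic head phantom specification
#'
#' The phantom stands in for a skull-stripped T1-weighted MRI plus its
#' parcellation: two mirror-symmetric hemispheres (cortical gray matter
#' shell over white matter), ellipsoidal lateral ventricles near the centre,
#' a brainstem and a cerebellum inferiorly, and empty background. Per-tissue
#' intensities are Gaussian with T1-like ordering WM > GM > CSF.
#'
#' @param shape Grid shape in voxels (default 96^3).
#' @param spacing Isotropic voxel spacing in mm (default 2).
#' @param brain_radii Cerebrum semiaxes in mm (x, y, z).
#' @param ventricle_radii Per-ventricle semiaxes in mm.
#' @param ventricle_offset Ventricle centre offset from the midline, mm.
#' @param brainstem_radii,cerebellum_radii Semiaxes of the inferior
#'   structures, mm.
#' @param gm_thickness Cortical shell thickness, mm.
#' @param intensities Named list of per-tissue means (arbitrary units).
#' @param noise_sd Per-tissue intensity standard deviation.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing = 2,
                         brain_radii = c(65, 80, 60),
                         ventricle_radii = c(6, 18, 10),
                         ventricle_offset = 10,
                         brainstem_radii = c(10, 10, 22),
                         cerebellum_radii = c(28, 20, 16),
                         gm_thickness = 8,
                         intensities = list(wm = 120, gm = 90, csf = 30,
                                            background = 0),
                         noise_sd = 5) {
  if (any(ventricle_radii + ventricle_offset > brain_radii))
    stop_resectr("ventricles must nest inside the brain", "resectr_bad_phantom")
  if (gm_thickness <= 0 || any(brain_radii <= gm_thickness))
    stop_resectr("cortical shell must be thinner than the brain",
                 "resectr_bad_phantom")
  if (length(unique(unlist(intensities))) != length(intensities))
    stop_resectr("tissue intensity means must be distinct", "resectr_bad_phantom")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 brain_radii = brain_radii, ventricle_radii = ventricle_radii,
                 ventricle_offset = ventricle_offset,
                 brainstem_radii = brainstem_radii,
                 cerebellum_radii = cerebellum_radii,
                 gm_thickness = gm_thickness, intensities = intensities,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Label table used by the phantom parcellation
#' @return A [label_table()] for the labels written by [make_phantom()].
#' @export
phantom_label_table <- function() {
  label_table(background = 0L, brainstem = 7L, cerebellum = 8L,
              gm_left = 1L, gm_right = 2L,
              hemisphere_left = c(1L, 3L, 5L),
              hemisphere_right = c(2L, 4L, 6L),
              ventricles = c(5L, 6L))
}

#' Generate a synthetic head phantom
#'
#' Geometry is deterministic given the spec; intensities are drawn from R's
#' global random number stream (`set.seed()` for reproducibility).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (`scalar_volume`), `parcellation`
#'   (`label_volume`) and `label_table`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  affine <- diag(c(rep(spec$spacing, 3), 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * spec$spacing
  grid <- image_grid(shape, affine)

  ax <- (seq_len(shape[1]) - 1 - (shape[1] - 1) / 2) * spec$spacing
  ay <- (seq_len(shape[2]) - 1 - (shape[2] - 1) / 2) * spec$spacing
  az <- (seq_len(shape[3]) - 1 - (shape[3] - 1) / 2) * spec$spacing
  X <- array(ax, dim = shape)
  Y <- array(rep(ay, each = shape[1]), dim = shape)
  Z <- array(rep(az, each = shape[1] * shape[2]), dim = shape)

  ellipsoid <- function(centre, radii) {
    ((X - centre[1]) / radii[1])^2 + ((Y - centre[2]) / radii[2])^2 +
      ((Z - centre[3]) / radii[3])^2 <= 1
  }

  # cerebrum sits above the inferior structures
  cz <- spec$brain_radii[3] * 0.25
  cerebrum <- ellipsoid(c(0, 0, cz), spec$brain_radii)
  inner <- ellipsoid(c(0, 0, cz), spec$brain_radii - spec$gm_thickness)
  shell <- cerebrum & !inner

  vent_l <- ellipsoid(c(-spec$ventricle_offset, 0, cz), spec$ventricle_radii)
  vent_r <- ellipsoid(c(spec$ventricle_offset, 0, cz), spec$ventricle_radii)

  bz <- cz - spec$brain_radii[3]
  brainstem <- ellipsoid(c(0, 10, bz), spec$brainstem_radii)
  cerebellum <- ellipsoid(c(0, -spec$brain_radii[2] * 0.45, bz + 5),
                          spec$cerebellum_radii)

  lab <- array(0L, dim = shape)
  left <- X < 0
  lab[cerebrum & shell & left] <- 1L   # cortical GM, left
  lab[cerebrum & shell & !left] <- 2L
  lab[cerebrum & inner & left] <- 3L   # white matter, left
  lab[cerebrum & inner & !left] <- 4L
  lab[vent_l] <- 5L
  lab[vent_r] <- 6L
  lab[brainstem & !cerebrum] <- 7L
  lab[cerebellum & !cerebrum & !(brainstem & !cerebrum)] <- 8L

  means <- c(spec$intensities$background,        # 0 background
             spec$intensities$gm, spec$intensities$gm,    # 1, 2
             spec$intensities$wm, spec$intensities$wm,    # 3, 4
             spec$intensities$csf, spec$intensities$csf,  # 5, 6
             spec$intensities$wm, spec$intensities$gm)    # 7 brainstem, 8 cerebellum
  vals <- means[lab + 1L] + stats::rnorm(length(lab), 0, spec$noise_sd)
  vals[lab == 0L] <- pmax(vals[lab == 0L], 0)

  tab <- phantom_label_table()
  list(image = scalar_volume(array(vals, dim = shape), grid),
       parcellation = label_volume(lab, grid, tab),
       label_table = tab)
}
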