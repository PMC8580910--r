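#' @useDynLib resectr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stop_resectr <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "resectr_error", "error")))
}

#' Image grid: voxel lattice bound to physical space
#'
#' A grid couples an array shape to a 4x4 affine that maps 0-based voxel
#' indices to physical RAS+ coordinates in millimetres. A voxel's physical
#' position is the position of its centre.
#'
#' @param shape Integer vector of length 3 (voxels per axis).
#' @param affine 4x4 voxel-index-to-mm matrix; must be invertible.
#' @return An object of class `image_grid` with fields `shape` and `affine`.
#' @export
image_grid <- function(shape, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_resectr("shape must be 3 positive integers", "resectr_bad_grid")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(shape - 1L) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop_resectr("affine must be a finite 4x4 matrix", "resectr_bad_grid")
  if (abs(det(affine)) < 1e-12)
    stop_resectr("affine must be invertible", "resectr_singular_affine")
  structure(list(shape = shape, affine = affine), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(grid_spacing(x), 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Per-axis voxel spacing of a grid, in mm
#' @param grid An `image_grid`.
#' @return Numeric vector of length 3.
#' @export
grid_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' The canonical 1 mm MNI-style grid (193 x 229 x 193)
#'
#' All resampling targets this grid: 1 mm isotropic spacing with the origin
#' at the grid centre, RAS+ orientation.
#' @return An `image_grid`.
#' @export
mni_grid <- function() {
  image_grid(c(193L, 229L, 193L))
}

#' Physical coordinates of voxel centres
#' @param grid An `image_grid`.
#' @param index Matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, index) {
  index <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  h <- cbind(index, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

new_volume <- function(values, grid, class) {
  if (!inherits(grid, "image_grid"))
    stop_resectr("grid must be an image_grid", "resectr_bad_grid")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop_resectr("value array shape does not match the grid", "resectr_grid_mismatch")
  structure(list(values = values, grid = grid), class = c(class, "volume"))
}

#' Scalar volume (real-valued image on a grid)
#' @param values 3D numeric array matching `grid$shape`; must be finite.
#' @param grid An `image_grid`.
#' @return A `scalar_volume`.
#' @export
scalar_volume <- function(values, grid) {
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop_resectr("scalar volume values must be finite", "resectr_nonfinite")
  new_volume(values, grid, "scalar_volume")
}

#' Binary mask (values exactly 0 or 1)
#' @param values 3D array of 0/1 (or logical) values matching `grid$shape`.
#' @param grid An `image_grid`.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(values, grid) {
  if (is.logical(values)) {
    v <- array(as.integer(values), dim = dim(values))
  } else {
    v <- values
    storage.mode(v) <- "integer"
    if (!isTRUE(all(values == v)) || !all(v %in% c(0L, 1L)))
      stop_resectr("mask values must be exactly 0 or 1", "resectr_bad_mask")
  }
  new_volume(v, grid, "binary_mask")
}

#' Integer label volume with its label table
#' @param values 3D array of non-negative integer labels.
#' @param grid An `image_grid`.
#' @param label_table A [label_table()] describing structure roles, or NULL.
#' @return A `label_volume`.
#' @export
label_volume <- function(values, grid, label_table = NULL) {
  v <- values
  storage.mode(v) <- "integer"
  if (anyNA(v) || any(v < 0L))
    stop_resectr("labels must be non-negative integers", "resectr_bad_labels")
  vol <- new_volume(v, grid, "label_volume")
  if (!is.null(label_table)) {
    known <- sort(unique(unlist(unclass(label_table), use.names = FALSE)))
    present <- sort(unique(as.vector(v)))
    if (!all(present %in% known))
      stop_resectr(sprintf("labels not in the label table: %s",
                           paste(setdiff(present, known), collapse = ", ")),
                   "resectr_unknown_label")
  }
  vol$label_table <- label_table
  vol
}

#' @export
print.volume <- function(x, ...) {
  cat("<", class(x)[1], "> ", paste(x$grid$shape, collapse = " x "),
      ", range [", signif(min(x$values), 5), ", ", signif(max(x$values), 5),
      "]\n", sep = "")
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param kind `"auto"` (integer-typed files become label volumes),
#'   `"scalar"`, or `"label"`.
#' @param label_table Optional [label_table()] attached when a label volume
#'   is returned.
#' @return A `scalar_volume` or `label_volume`.
#' @export
read_nifti <- function(path, kind = c("auto", "scalar", "label"),
                       label_table = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop_resectr(sprintf("file not found: %s", path), "resectr_missing_file")
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_resectr(
                    sprintf("not a NIfTI volume: %s", path), "resectr_bad_nifti"))
  arr <- as.array(img)
  dims <- dim(arr)
  if (length(dims) == 4L && dims[4] == 1L) {
    arr <- arr[, , , 1]
    dims <- dim(arr)
  }
  if (length(dims) != 3L)
    stop_resectr("expected a 3D volume", "resectr_not_3d")
  attributes(arr) <- list(dim = dims)
  affine <- structure(RNifti::xform(img), code = NULL)
  grid <- image_grid(dims, matrix(as.numeric(affine), 4, 4))
  int_codes <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)
  is_int <- (RNifti::niftiHeader(img)$datatype %in% int_codes) &&
    isTRUE(all(arr == round(arr)))
  if (kind == "label" || (kind == "auto" && is_int)) {
    label_volume(arr, grid, label_table)
  } else {
    scalar_volume(arr, grid)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume as NIfTI
#'
#' Masks and label volumes are written with an integer datatype; scalar
#' volumes as 32-bit float.
#' @param volume A `scalar_volume`, `binary_mask` or `label_volume`.
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    stop_resectr(sprintf("directory does not exist: %s", dirname(path)),
                 "resectr_unwritable")
  integer_like <- inherits(volume, "binary_mask") || inherits(volume, "label_volume")
  arr <- volume$values
  storage.mode(arr) <- if (integer_like) "integer" else "double"
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(volume$grid$affine, code = 2L))
  pixdim <- grid_spacing(volume$grid)
  RNifti::writeNifti(img, path,
                     datatype = if (integer_like) "int32" else "float")
  invisible(path)
}

#' Resample a volume onto the canonical MNI-style grid
#'
#' Scalar volumes are interpolated with Lanczos-windowed sinc (radius 4
#' voxels, weights renormalised to unit sum over in-bounds taps); masks and
#' label volumes use nearest-neighbour interpolation, which introduces no new
#' label values. `affine_to_mni` is the physical-space map taking input mm
#' coordinates to MNI mm coordinates (identity for data already aligned).
#'
#' @param volume A `scalar_volume`, `binary_mask` or `label_volume`.
#' @param affine_to_mni Invertible 4x4 physical-space affine.
#' @param grid Target grid, by default [mni_grid()].
#' @return A volume of the same class on `grid`.
#' @export
resample_to_mni <- function(volume, affine_to_mni = diag(4), grid = mni_grid()) {
  UseMethod("resample_to_mni")
}

index_map <- function(src_grid, affine_to_mni, tgt_grid) {
  affine_to_mni <- as.matrix(affine_to_mni)
  if (!all(dim(affine_to_mni) == c(4, 4)) || abs(det(affine_to_mni)) < 1e-12)
    stop_resectr("affine_to_mni must be an invertible 4x4 matrix",
                 "resectr_singular_affine")
  solve(src_grid$affine) %*% solve(affine_to_mni) %*% tgt_grid$affine
}

#' @export
resample_to_mni.scalar_volume <- function(volume, affine_to_mni = diag(4),
                                          grid = mni_grid()) {
  map <- index_map(volume$grid, affine_to_mni, grid)
  vals <- resample_lanczos_cpp(as.vector(volume$values), volume$grid$shape,
                               map, grid$shape)
  scalar_volume(array(vals, dim = grid$shape), grid)
}

#' @export
resample_to_mni.binary_mask <- function(volume, affine_to_mni = diag(4),
                                        grid = mni_grid()) {
  map <- index_map(volume$grid, affine_to_mni, grid)
  vals <- resample_nearest_cpp(as.numeric(volume$values), volume$grid$shape,
                               map, grid$shape)
  binary_mask(array(as.integer(vals), dim = grid$shape), grid)
}

#' @export
resample_to_mni.label_volume <- function(volume, affine_to_mni = diag(4),
                                         grid = mni_grid()) {
  map <- index_map(volume$grid, affine_to_mni, grid)
  vals <- resample_nearest_cpp(as.numeric(volume$values), volume$grid$shape,
                               map, grid$shape)
  label_volume(array(as.integer(vals), dim = grid$shape), grid,
               volume$label_table)
}
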