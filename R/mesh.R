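#' Triangle mesh in physical coordinates
#'
#' Vertices are in mm; faces are 1-based vertex index triples with
#' consistent outward winding.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @return A `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L || !all(is.finite(vertices)))
    stop_resectr("vertices must be a finite n x 3 matrix", "resectr_bad_mesh")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop_resectr("face indices out of range", "resectr_bad_mesh")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

#' Is every edge shared by exactly two faces?
#' @param mesh A `triangle_mesh`.
#' @return TRUE if the mesh is closed with consistent winding.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  directed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(directed[, 1], directed[, 2])
  if (anyDuplicated(key_dir) > 0L) return(FALSE) # inconsistent winding
  key_undir <- paste(pmin(directed[, 1], directed[, 2]),
                     pmax(directed[, 1], directed[, 2]))
  all(table(key_undir) == 2L)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh A `triangle_mesh` with outward winding.
#' @return Signed volume in mm^3 (positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
                 b[, 3] * c[, 1] - b[, 1] * c[, 3],
                 b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cross)) / 6
}

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

#' Geodesic sphere (subdivided icosahedron)
#'
#' Subdivides each icosahedron edge `f` times and projects every vertex onto
#' the unit sphere, giving 10f^2 + 2 vertices and 20f^2 faces.
#'
#' @param f Geodesic frequency (positive integer).
#' @return A watertight unit-sphere `triangle_mesh` centred at the origin.
#' @export
geodesic_sphere <- function(f) {
  f <- as.integer(f)
  if (is.na(f) || f < 1L)
    stop_resectr("frequency f must be a positive integer", "resectr_bad_frequency")
  ico <- icosahedron()
  if (f == 1L) {
    v <- ico$vertices / sqrt(rowSums(ico$vertices^2))
    return(triangle_mesh(v, ico$faces))
  }
  vkey <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  nvert <- 0L
  get_vertex <- function(p) {
    # p is the unprojected lattice point; identical across adjacent faces
    # bit-for-bit (integer-weighted sums of shared corner coordinates), so an
    # exact key is safe.
    key <- paste(sprintf("%.17g", p), collapse = ",")
    idx <- vkey[[key]]
    if (is.null(idx)) {
      nvert <<- nvert + 1L
      verts[[nvert]] <<- p / sqrt(sum(p^2))
      vkey[[key]] <- nvert
      idx <- nvert
    }
    idx
  }
  faces <- vector("list", 20L * f^2)
  nf <- 0L
  for (t in seq_len(nrow(ico$faces))) {
    corner <- ico$vertices[ico$faces[t, ], , drop = FALSE]
    # lattice index grid for this face
    idx <- matrix(NA_integer_, f + 1L, f + 1L)
    for (i in 0:f) {
      for (j in 0:(f - i)) {
        p <- corner[1, ] * (f - i - j) + corner[2, ] * i + corner[3, ] * j
        idx[i + 1L, j + 1L] <- get_vertex(p / f)
      }
    }
    for (i in 0:(f - 1L)) {
      for (j in 0:(f - 1L - i)) {
        nf <- nf + 1L
        faces[[nf]] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L],
                         idx[i + 1L, j + 2L])
        if (i + j <= f - 2L) {
          nf <- nf + 1L
          faces[[nf]] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L],
                           idx[i + 1L, j + 2L])
        }
      }
    }
  }
  triangle_mesh(do.call(rbind, verts), do.call(rbind, faces[seq_len(nf)]))
}

#' Displace mesh vertices radially by procedural noise
#'
#' Each vertex v is replaced by v + delta(v) * v / ||v||, where delta is the
#' noise displacement; faces are unchanged.
#'
#' @param mesh A `triangle_mesh` with no vertex at the origin.
#' @param field A [noise_field()], or (for testing and extension) a function
#'   taking the n x 3 vertex matrix and returning n displacements.
#' @param params A [fractal_params()]; ignored when `field` is a function.
#' @return The perturbed `triangle_mesh`.
#' @export
perturb_radially <- function(mesh, field, params = fractal_params()) {
  v <- mesh$vertices
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12))
    stop_resectr("mesh has a vertex at the origin", "resectr_degenerate_vertex")
  delta <- if (is.function(field)) field(v) else vertex_displacement(field, v, params)
  triangle_mesh(v + (delta / nrm) * v, mesh$faces)
}

#' Ellipsoid semiaxes for a target cavity volume
#'
#' Computes (r1, r2, r3) = (r, lambda * r, r / lambda). In `"volume-exact"`
#' mode (default) r = (3 v / (4 pi))^(1/3), so the ellipsoid encloses exactly
#' `v`; `"paper-literal"` mode uses r = (3 v / 4)^(1/3), the printed formula
#' without the factor of pi.
#'
#' @param v Target volume in mm^3 (> 0).
#' @param lambda Semiaxis ratio (>= 1).
#' @param mode `"volume-exact"` or `"paper-literal"`.
#' @return Numeric vector (r1, r2, r3) in mm.
#' @export
semiaxes <- function(v, lambda = 1, mode = c("volume-exact", "paper-literal")) {
  mode <- match.arg(mode)
  if (!is.finite(v) || v <= 0)
    stop_resectr("volume must be positive", "resectr_bad_volume")
  if (!is.finite(lambda) || lambda < 1)
    stop_resectr("lambda must be >= 1", "resectr_bad_volume")
  r <- if (mode == "volume-exact") (3 * v / (4 * pi))^(1 / 3) else (3 * v / 4)^(1 / 3)
  c(r, lambda * r, r / lambda)
}

rotation_xyz <- function(theta) {
  cx <- cos(theta[1]); sx <- sin(theta[1])
  cy <- cos(theta[2]); sy <- sin(theta[2])
  cz <- cos(theta[3]); sz <- sin(theta[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rx %*% ry %*% rz
}

#' Cavity shape parameters
#'
#' @param mode `"noisy"`, `"ellipsoid"` or `"cuboid"` (the shape-complexity
#'   ablation modes).
#' @param volume Target volume v in mm^3.
#' @param ratio Semiaxis ratio lambda (>= 1).
#' @param angles Rotations (theta_x, theta_y, theta_z) in radians.
#' @param frequency Geodesic frequency f.
#' @param semiaxes_mode Passed to [semiaxes()].
#' @return A `shape_params` object.
#' @export
shape_params <- function(mode = c("noisy", "ellipsoid", "cuboid"),
                         volume = 10000, ratio = 1, angles = c(0, 0, 0),
                         frequency = 16L,
                         semiaxes_mode = c("volume-exact", "paper-literal")) {
  mode <- match.arg(mode)
  semiaxes_mode <- match.arg(semiaxes_mode)
  if (!is.finite(volume) || volume <= 0)
    stop_resectr("volume must be positive", "resectr_bad_volume")
  if (!is.finite(ratio) || ratio < 1)
    stop_resectr("ratio must be >= 1", "resectr_bad_volume")
  frequency <- as.integer(frequency)
  if (is.na(frequency) || frequency < 1L)
    stop_resectr("frequency must be >= 1", "resectr_bad_frequency")
  structure(list(mode = mode, volume = volume, ratio = ratio,
                 angles = as.numeric(angles), frequency = frequency,
                 semiaxes_mode = semiaxes_mode),
            class = "shape_params")
}

cuboid_mesh <- function(half) {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  v <- sweep(s, 2, half, "*")
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (z = -h3)
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front (y = -h2)
             c(2, 3, 7), c(2, 7, 6),   # right
             c(3, 4, 8), c(3, 8, 7),   # back
             c(4, 1, 5), c(4, 5, 8))   # left
  triangle_mesh(v, f)
}

#' Rotate and scale the cavity mesh to its target size
#'
#' For `"noisy"` and `"ellipsoid"` modes applies the rotation (about x, y, z
#' in that order) followed by anisotropic scaling with the semiaxes along
#' the fixed axes. In `"cuboid"` mode the mesh is replaced by an axis-aligned
#' box with edge lengths (2 r1, 2 r2, 2 r3); cuboids are never rotated.
#'
#' @param mesh A watertight origin-centred `triangle_mesh`.
#' @param params A [shape_params()].
#' @param order `"rotate-then-scale"` (default) or `"scale-then-rotate"`,
#'   for sensitivity checks of the composition reading.
#' @return The transformed `triangle_mesh`.
#' @export
shape_transform <- function(mesh, params,
                            order = c("rotate-then-scale", "scale-then-rotate")) {
  order <- match.arg(order)
  stopifnot(inherits(params, "shape_params"))
  if (!mesh_is_watertight(mesh))
    stop_resectr("mesh is not watertight", "resectr_open_mesh")
  r <- semiaxes(params$volume, params$ratio, params$semiaxes_mode)
  if (params$mode == "cuboid") return(cuboid_mesh(r))
  rot <- rotation_xyz(params$angles)
  m <- if (order == "rotate-then-scale") diag(r) %*% rot else rot %*% diag(r)
  triangle_mesh(mesh$vertices %*% t(m), mesh$faces)
}

#' Translate a mesh to centre it on a seed point
#' @param mesh A `triangle_mesh` centred at the origin (model-space centre).
#' @param a Target centre in mm (length-3).
#' @return The translated `triangle_mesh`.
#' @export
translate_to_seed <- function(mesh, a) {
  if (length(a) != 3L || !all(is.finite(a)))
    stop_resectr("seed point must be a finite 3-vector", "resectr_bad_point")
  triangle_mesh(sweep(mesh$vertices, 2, as.numeric(a), "+"), mesh$faces)
}

#' Voxelize a closed mesh onto an image grid
#'
#' A voxel is set iff its centre lies inside the closed surface, decided by
#' the even-odd (parity) rule along grid-aligned rays.
#'
#' @param mesh A watertight `triangle_mesh` in mm coordinates.
#' @param grid The target `image_grid`.
#' @return A `binary_mask` on `grid`.
#' @export
voxelize <- function(mesh, grid) {
  if (!mesh_is_watertight(mesh))
    stop_resectr("mesh is not watertight", "resectr_open_mesh")
  inv <- solve(grid$affine)
  vidx <- cbind(mesh$vertices, 1) %*% t(inv)
  inside <- voxelize_parity_cpp(vidx[, 1:3, drop = FALSE], mesh$faces - 1L,
                                grid$shape)
  binary_mask(array(as.integer(inside), dim = grid$shape), grid)
}

#' Export a mesh as an ASCII PLY file (debugging aid)
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh$vertices, trim = TRUE), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
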