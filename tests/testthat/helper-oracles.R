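# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the simplex reference is a plain-R
# transliteration of Gustavson's published algorithm, point-in-mesh uses the
# generalized winding number (solid angles) instead of parity ray casting,
# and the Gaussian kernel oracle builds the separable kernel explicitly.

ref_grad3 <- rbind(
  c(1, 1, 0), c(-1, 1, 0), c(1, -1, 0), c(-1, -1, 0),
  c(1, 0, 1), c(-1, 0, 1), c(1, 0, -1), c(-1, 0, -1),
  c(0, 1, 1), c(0, -1, 1), c(0, 1, -1), c(0, -1, -1))

# Reference single-point 3D simplex noise (Gustavson), perm = 512 ints.
ref_simplex3 <- function(xin, yin, zin, perm) {
  F3 <- 1 / 3
  G3 <- 1 / 6
  s <- (xin + yin + zin) * F3
  i <- floor(xin + s); j <- floor(yin + s); k <- floor(zin + s)
  t <- (i + j + k) * G3
  x0 <- xin - (i - t); y0 <- yin - (j - t); z0 <- zin - (k - t)
  if (x0 >= y0) {
    if (y0 >= z0)      { o1 <- c(1, 0, 0); o2 <- c(1, 1, 0) }
    else if (x0 >= z0) { o1 <- c(1, 0, 0); o2 <- c(1, 0, 1) }
    else               { o1 <- c(0, 0, 1); o2 <- c(1, 0, 1) }
  } else {
    if (y0 < z0)       { o1 <- c(0, 0, 1); o2 <- c(0, 1, 1) }
    else if (x0 < z0)  { o1 <- c(0, 1, 0); o2 <- c(0, 1, 1) }
    else               { o1 <- c(0, 1, 0); o2 <- c(1, 1, 0) }
  }
  d0 <- c(x0, y0, z0)
  d1 <- d0 - o1 + G3
  d2 <- d0 - o2 + 2 * G3
  d3 <- d0 - 1 + 3 * G3
  # 1-based indexing into the 0-based table
  pidx <- function(v) perm[v + 1]
  iw <- bitwAnd(as.integer(i), 255L)
  jw <- bitwAnd(as.integer(j), 255L)
  kw <- bitwAnd(as.integer(k), 255L)
  gi <- c(
    pidx(iw + pidx(jw + pidx(kw))) %% 12,
    pidx(iw + o1[1] + pidx(jw + o1[2] + pidx(kw + o1[3]))) %% 12,
    pidx(iw + o2[1] + pidx(jw + o2[2] + pidx(kw + o2[3]))) %% 12,
    pidx(iw + 1 + pidx(jw + 1 + pidx(kw + 1))) %% 12) + 1
  corners <- rbind(d0, d1, d2, d3)
  n <- 0
  for (c_ in 1:4) {
    tt <- 0.6 - sum(corners[c_, ]^2)
    if (tt > 0) n <- n + tt^4 * sum(ref_grad3[gi[c_], ] * corners[c_, ])
  }
  32 * n
}

# Generalized winding number: is each point inside the closed mesh?
# Van Oosterom & Strackee solid-angle formula, summed over faces.
winding_inside <- function(points, mesh) {
  total <- numeric(nrow(points))
  v <- mesh$vertices
  f <- mesh$faces
  for (t in seq_len(nrow(f))) {
    a <- sweep(points, 2, v[f[t, 1], ], "-") * -1
    b <- sweep(points, 2, v[f[t, 2], ], "-") * -1
    c_ <- sweep(points, 2, v[f[t, 3], ], "-") * -1
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c_^2))
    num <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
           a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
           a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(b * c_) * la +
           rowSums(c_ * a) * lb
    total <- total + 2 * atan2(num, den)
  }
  abs(total) > 2 * pi # winding number > 1/2
}

# Brute-force voxel mask from the winding-number oracle.
winding_voxelize <- function(mesh, grid) {
  idx <- as.matrix(expand.grid(i = 0:(grid$shape[1] - 1),
                               j = 0:(grid$shape[2] - 1),
                               k = 0:(grid$shape[3] - 1)))
  centres <- voxel_to_mm(grid, idx)
  inside <- winding_inside(centres, mesh)
  array(as.integer(inside), dim = grid$shape)
}

# Explicit separable truncated-Gaussian kernel, unit sum.
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- ceiling(truncate * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# A small random watertight mesh: perturbed geodesic sphere, anisotropically
# scaled and shifted, sized to sit inside a grid of `extent` mm.
random_test_mesh <- function(extent = 24) {
  mesh <- geodesic_sphere(2)
  delta <- runif(nrow(mesh$vertices), -0.25, 0.25)
  mesh <- triangle_mesh(mesh$vertices * (1 + delta), mesh$faces)
  radii <- runif(3, extent / 8, extent / 3)
  centre <- runif(3, -extent / 8, extent / 8)
  triangle_mesh(sweep(mesh$vertices %*% diag(radii), 2, centre, "+"),
                mesh$faces)
}

coarse_phantom <- function(seed = 1, shape = c(64L, 64L, 64L), spacing = 3) {
  set.seed(seed)
  make_phantom(phantom_spec(shape = shape, spacing = spacing))
}
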