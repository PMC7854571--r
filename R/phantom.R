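## Synthetic 3D phantoms and their 2D projections.

#' Generate a synthetic 3D phantom
#'
#' Builds a cubic density as a sum of `nComponents` random primitives --
#' anisotropic Gaussian blobs or solid ellipsoids -- placed near the volume
#' centre, then normalizes the density to a maximum of 1.  The phantom
#' stands in for a macromolecular 3D structure; its projections provide
#' clean reference images for simulation.
#'
#' @param side integer edge length in voxels (at least 16).
#' @param nComponents number of primitives (at least 1; default 6, which
#'   gives projections a lumpy, protein-like level of structural detail).
#' @param seed integer; the phantom is deterministic given the seed.
#' @return A [PhantomVolume-class].
#' @examples
#' vol <- makePhantom(32, nComponents = 2, seed = 7)
#' vol
#' @export
makePhantom <- function(side, nComponents = 6L, seed = 1L) {
  side <- as.integer(side)
  nComponents <- as.integer(nComponents)
  if (side < 16L) stop("'side' must be at least 16")
  if (nComponents < 1L) stop("'nComponents' must be at least 1")

  comps <- withSeed(seed, lapply(seq_len(nComponents), function(i) {
    list(
      type = sample(c("gaussian", "ellipsoid"), 1L, prob = c(0.7, 0.3)),
      center = (side + 1) / 2 + runif(3, -side / 6, side / 6),
      axes = runif(3, side / 20, side / 9),
      rotation = randomRotation(),
      amplitude = runif(1, 0.5, 1))
  }))

  grid <- array(0, rep(side, 3L))
  for (cmp in comps) grid <- grid + evalComponent(cmp, side)
  grid <- grid / max(grid)
  new("PhantomVolume", grid = grid, side = side, components = comps)
}

# Density contribution of one primitive, evaluated on the full voxel grid.
evalComponent <- function(cmp, side) {
  ax <- seq_len(side)
  p <- rbind(rep(ax, times = side * side),
             rep(rep(ax, each = side), times = side),
             rep(ax, each = side * side))
  q <- diag(1 / cmp$axes) %*% cmp$rotation %*% (p - cmp$center)
  r2 <- colSums(q^2)
  v <- if (cmp$type == "gaussian") cmp$amplitude * exp(-0.5 * r2)
       else cmp$amplitude * (r2 <= 1)
  array(v, rep(side, 3L))
}

# A uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Rotation matrix from ZYZ Euler angles
#'
#' @param euler numeric length-3 vector of angles in degrees; the rotation
#'   is `Rz(euler[1]) %*% Ry(euler[2]) %*% Rz(euler[3])`.
#' @return A 3x3 rotation matrix.
#' @export
eulerMatrix <- function(euler) {
  a <- euler * pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3L)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3L)
  Rz(a[1]) %*% Ry(a[2]) %*% Rz(a[3])
}

#' Project a phantom along the viewing axis
#'
#' Rotates the volume about its centre by the ZYZ Euler angles (trilinear
#' interpolation, density outside the grid taken as zero) and sums along
#' the final z-axis, i.e. computes the line-integral projection image.
#' The returned image is unnormalized; dataset-level min-max normalization
#' is applied by [buildDatasets()] using the clean tier's range.
#'
#' @param volume a [PhantomVolume-class].
#' @param orientation numeric length-3 ZYZ Euler angles in degrees.
#' @return A `(side, side)` numeric matrix.
#' @examples
#' vol <- makePhantom(16, 1, seed = 1)
#' img <- projectVolume(vol, c(0, 90, 0))
#' @export
projectVolume <- function(volume, orientation) {
  stopifnot(is(volume, "PhantomVolume"))
  side <- volume@side
  R <- eulerMatrix(orientation)
  ctr <- (side + 1) / 2
  ax <- seq_len(side)
  p <- rbind(rep(ax, times = side * side),
             rep(rep(ax, each = side), times = side),
             rep(ax, each = side * side))
  # rotated volume v'(p) = v(R^T (p - ctr) + ctr)
  q <- crossprod(R, p - ctr) + ctr
  vals <- trilinear(volume@grid, q)
  rot <- array(vals, rep(side, 3L))
  rowSums(rot, dims = 2L)
}

# Vectorized trilinear interpolation; coords is a 3 x n matrix of 1-based
# positions, values outside the grid are zero.
trilinear <- function(grid, coords) {
  side <- dim(grid)[1]
  i0 <- floor(coords)
  f <- coords - i0
  out <- numeric(ncol(coords))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- i0[1, ] + dx; iy <- i0[2, ] + dy; iz <- i0[3, ] + dz
    w <- (if (dx) f[1, ] else 1 - f[1, ]) *
         (if (dy) f[2, ] else 1 - f[2, ]) *
         (if (dz) f[3, ] else 1 - f[3, ])
    ok <- ix >= 1 & ix <= side & iy >= 1 & iy <= side & iz >= 1 & iz <= side
    idx <- ix[ok] + (iy[ok] - 1) * side + (iz[ok] - 1) * side * side
    out[ok] <- out[ok] + w[ok] * grid[idx]
  }
  out
}

#' The four default viewing orientations
#'
#' A tilt series of four neighbouring views (tilt 40, 56, 72 and 88
#' degrees about the y-axis).  Nearby orientations produce gradually
#' varying projections, which is the realistic hard case for
#' orientation clustering: on clean projections the four classes
#' separate perfectly, while at SNR 0.1 raw-image clustering degrades
#' into the mid-range — the regime where denoising decides the
#' clustering outcome.
#'
#' @return A `(4, 3)` matrix of ZYZ Euler angles in degrees.
#' @export
defaultOrientations <- function() {
  matrix(c(0, 40, 0,
           0, 56, 0,
           0, 72, 0,
           0, 88, 0), ncol = 3L, byrow = TRUE)
}
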