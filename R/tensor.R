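#' Diffusion tensor volume
#'
#' A 3D grid of symmetric 3x3 diffusion tensors with a voxel-to-world
#' affine. Tensors are stored internally in lower-triangular row order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the common on-disk dialect; readers
#' accept the upper-triangular order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) via an
#' explicit flag -- the two dialects are never guessed.
#'
#' @param tensors 4D numeric array, `nx x ny x nz x 6`, mm^2/s.
#' @param affine invertible 4x4 voxel-to-world transform (0-based voxel
#'   indices map to world mm).
#' @param order component order of the supplied array: "lower" (default)
#'   or "upper".
#' @return An object of class `dt_volume` with elements `tensors` (lower
#'   order), `affine`, `dim`.
#' @export
dt_volume <- function(tensors, affine, order = c("lower", "upper")) {
  order <- match.arg(order)
  tensors <- as.array(tensors)
  if (length(dim(tensors)) != 4L || dim(tensors)[4] != 6L)
    stop("'tensors' must be an nx x ny x nz x 6 array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)))
    stop("'affine' must be 4 x 4")
  if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
  if (order == "upper")
    tensors <- tensors[, , , c(1L, 2L, 4L, 3L, 5L, 6L), drop = FALSE]
  structure(list(tensors = tensors, affine = affine,
                 dim = dim(tensors)[1:3]),
            class = "dt_volume")
}

#' @export
print.dt_volume <- function(x, ...) {
  cat(sprintf("Diffusion tensor volume: %s grid, voxel %s mm\n",
              paste(x$dim, collapse = " x "),
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3),
                    collapse = " x ")))
  invisible(x)
}

# lower-triangular six-vector <-> symmetric matrix
tensor6_to_mat <- function(d) {
  matrix(c(d[1], d[2], d[4],
           d[2], d[3], d[5],
           d[4], d[5], d[6]), 3, 3)
}

mat_to_tensor6 <- function(m) c(m[1, 1], m[1, 2], m[2, 2],
                                m[1, 3], m[2, 3], m[3, 3])

.as_tensor6 <- function(tensor, tol = 1e-6) {
  if (is.matrix(tensor)) {
    if (!all(dim(tensor) == c(3, 3)))
      stop("tensor must be 3 x 3 or a length-6 vector")
    scale <- max(abs(tensor), 1e-300)
    if (max(abs(tensor - t(tensor))) > tol * scale)
      stop("tensor is not symmetric")
    mat_to_tensor6((tensor + t(tensor)) / 2)
  } else if (length(tensor) == 6L) {
    as.numeric(tensor)
  } else stop("tensor must be 3 x 3 or a length-6 vector")
}

# Closed-form eigenvalues of many symmetric 3x3 tensors (rows of an
# N x 6 lower-order matrix), descending. Trigonometric (Cardano) form;
# matches base eigen() to near machine precision and is vastly cheaper
# inside the projection loop.
eig3sym <- function(D6) {
  D6 <- if (is.null(dim(D6))) matrix(D6, ncol = 6) else D6
  a11 <- D6[, 1]; a12 <- D6[, 2]; a22 <- D6[, 3]
  a13 <- D6[, 4]; a23 <- D6[, 5]; a33 <- D6[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  p2 <- b11^2 + b22^2 + b33^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  detB <- b11 * (b22 * b33 - a23^2) -
    a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / 2 / pmax(p^3, 1e-300), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  cbind(l1, l2, l3)
}

#' Fractional anisotropy of a diffusion tensor
#'
#' FA is the normalized dispersion of the tensor eigenvalues,
#' \deqn{FA = \sqrt{3/2}\,\frac{\|\lambda - \bar\lambda\|}{\|\lambda\|},}
#' dimensionless in \[0, 1\]. Negative eigenvalues (possible in noisy or
#' synthetic tensors) are clipped to zero before the formula so FA stays
#' bounded; the all-zero tensor returns FA = 0 by convention.
#'
#' @param tensor symmetric 3x3 matrix (mm^2/s) or length-6 lower-order
#'   vector (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#' @return FA in \[0, 1\].
#' @seealso [compute_md()]
#' @export
compute_fa <- function(tensor) {
  d6 <- .as_tensor6(tensor)
  as.vector(.fa_from_six(matrix(d6, ncol = 6)))
}

.fa_from_six <- function(D6) {
  ev <- eig3sym(D6)
  ev[ev < 0] <- 0
  ss <- rowSums(ev^2)
  mu <- rowMeans(ev)
  num <- rowSums((ev - mu)^2)
  ifelse(ss <= 0, 0, sqrt(1.5 * num / ss))
}

#' Mean diffusivity of a diffusion tensor
#'
#' MD = trace / 3, in mm^2/s.
#'
#' @inheritParams compute_fa
#' @export
compute_md <- function(tensor) {
  d6 <- .as_tensor6(tensor)
  (d6[1] + d6[3] + d6[6]) / 3
}

.md_from_six <- function(D6) (D6[, 1] + D6[, 3] + D6[, 6]) / 3

#' Interpolate tensors at world coordinates
#'
#' Component-wise trilinear interpolation of the six unique tensor
#' components at arbitrary world-mm points. Points whose interpolation
#' stencil leaves the grid return NA rows (treated as missing samples
#' downstream, never zero-filled).
#'
#' Interpolation is deliberately linear per component (not Log-Euclidean):
#' at voxel scale the difference is second order and the linear scheme is
#' determinate and reproducible bit for bit.
#'
#' @param volume a [dt_volume()].
#' @param points numeric n x 3 matrix (or length-3 vector) of world mm
#'   coordinates.
#' @return n x 6 matrix of lower-order tensor components; NA rows mark
#'   out-of-bounds points.
#' @export
interpolate_tensor <- function(volume, points) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else
    as.matrix(points)
  n <- nrow(pts)
  inv <- solve(volume$affine)
  vox <- cbind(pts, 1) %*% t(inv)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  dm <- volume$dim
  ok <- x >= 0 & x <= dm[1] - 1 & y >= 0 & y <= dm[2] - 1 &
    z >= 0 & z <= dm[3] - 1 & is.finite(x) & is.finite(y) & is.finite(z)
  out <- matrix(NA_real_, n, 6)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), dm[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), dm[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), dm[3] - 2); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  tn <- volume$tensors
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  base <- x0 + y0 * nx + z0 * nxy  # 0-based linear index of corner
  acc <- matrix(0, sum(ok), 6)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) *
      (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    idx <- base + dx + dy * nx + dz * nxy + 1
    for (c6 in 1:6)
      acc[, c6] <- acc[, c6] + w * tn[idx + (c6 - 1) * nxy * dm[3]]
  }
  out[ok, ] <- acc
  out
}

#' Read and write diffusion tensor volumes as NIfTI-1
#'
#' Tensors are stored as a 4D NIfTI with six volumes. The voxel-to-world
#' affine is taken from the sform when set, otherwise the qform (sform
#' priority). The component order on disk must be declared explicitly.
#'
#' @param volume a [dt_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param order on-disk component order, "lower" or "upper".
#' @return `read_tensor_nifti` returns a [dt_volume()];
#'   `write_tensor_nifti` returns `path` invisibly.
#' @export
write_tensor_nifti <- function(volume, path, order = c("lower", "upper")) {
  order <- match.arg(order)
  arr <- volume$tensors
  if (order == "upper")
    arr <- arr[, , , c(1L, 2L, 4L, 3L, 5L, 6L), drop = FALSE]
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_tensor_nifti
#' @export
read_tensor_nifti <- function(path, order = c("lower", "upper")) {
  order <- match.arg(order)
  img <- RNifti::readNifti(path)
  affine <- RNifti::xform(img, useQuaternionFirst = FALSE)
  arr <- array(as.vector(img), dim = dim(img))
  dt_volume(arr, matrix(as.vector(affine), 4, 4), order = order)
}

#' Scalar FA / MD maps of a tensor volume
#'
#' @param volume a [dt_volume()].
#' @return 3D array of FA (dimensionless) or MD (mm^2/s).
#' @export
fa_map <- function(volume) {
  d <- volume$dim
  D6 <- matrix(volume$tensors, ncol = 6)
  array(.fa_from_six(D6), dim = d)
}

#' @rdname fa_map
#' @export
md_map <- function(volume) {
  d <- volume$dim
  D6 <- matrix(volume$tensors, ncol = 6)
  array(.md_from_six(D6), dim = d)
}
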