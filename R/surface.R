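#' Medial tract surface
#'
#' Construct a medial (skeleton) surface: a triangulated 2-manifold with
#' boundary carrying a per-vertex radius field. Together with the radius,
#' the skeleton fully encodes the tract geometry: the two boundary sheets
#' are recovered by inverse skeletonization (see [build_spokes()]).
#'
#' Validation enforces the medial-model invariants: the triangulation must
#' be a connected manifold with no degenerate (zero-area) triangles, the
#' radius must be strictly positive everywhere, and vertex normals (area
#' weighted averages of incident triangle normals) are computed and
#' normalized to unit length. Medial feasibility (tangential radius
#' gradient of norm at most 1) is *not* enforced here; it is assessed per
#' vertex by [build_spokes()], which flags and excludes infeasible
#' vertices rather than failing.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in world mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices with
#'   consistent orientation.
#' @param radius numeric vector of length n, local tract half-thickness in
#'   mm; must be positive.
#' @param tract_name label for the tract (e.g. "CST").
#' @param hemisphere one of "left", "right", "midline".
#' @return An object of class `medial_surface`: a list with elements
#'   `vertices`, `triangles`, `radius`, `normals`, `tract_name`,
#'   `hemisphere`.
#' @seealso [build_spokes()], [heat_smooth()], [surface_area()]
#' @export
medial_surface <- function(vertices, triangles, radius,
                           tract_name = "tract",
                           hemisphere = c("midline", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("'vertices' must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("'triangles' must be an m x 3 matrix")
  n <- nrow(vertices)
  if (length(radius) != n) stop("'radius' must have one value per vertex")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("'radius' must be positive at every vertex")
  if (min(triangles) < 1L || max(triangles) > n)
    stop("triangle indices out of range")

  areas <- .triangle_areas(vertices, triangles)
  if (any(areas <= 1e-12))
    stop("degenerate (zero-area) triangles present")
  .check_manifold(triangles, n)

  normals <- .vertex_normals(vertices, triangles, areas)
  structure(list(vertices = vertices, triangles = triangles,
                 radius = as.numeric(radius), normals = normals,
                 tract_name = tract_name, hemisphere = hemisphere),
            class = "medial_surface")
}

#' @export
print.medial_surface <- function(x, ...) {
  cat(sprintf("Medial surface '%s' (%s): %d vertices, %d triangles\n",
              x$tract_name, x$hemisphere, nrow(x$vertices),
              nrow(x$triangles)))
  cat(sprintf("  area %.1f mm^2, radius %.2f-%.2f mm\n",
              surface_area(x), min(x$radius), max(x$radius)))
  invisible(x)
}

# per-triangle areas via cross products
.triangle_areas <- function(v, tr) {
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

# manifold-with-boundary check: every edge in at most 2 triangles,
# triangulation edge-connected
.check_manifold <- function(tr, n) {
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two triangles")
  # connectivity: breadth-first search over the one-ring graph
  used <- sort(unique(as.vector(tr)))
  if (length(used) < n) stop("mesh has isolated vertices")
  nb <- .one_rings(tr, n)
  seen <- logical(n)
  front <- 1L
  seen[1L] <- TRUE
  while (length(front)) {
    nxt <- unique(unlist(nb[front], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    front <- nxt
  }
  if (!all(seen)) stop("mesh is not connected")
  invisible(TRUE)
}

.vertex_normals <- function(v, tr, areas = NULL) {
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # cross-product magnitude is twice the area, so accumulation is
  # area-weighted automatically
  nv <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    nv[, 1] <- nv[, 1] + tabulate2(tr[, k], fn[, 1], nrow(v))
    nv[, 2] <- nv[, 2] + tabulate2(tr[, k], fn[, 2], nrow(v))
    nv[, 3] <- nv[, 3] + tabulate2(tr[, k], fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(nv^2))
  if (any(len < 1e-14)) stop("cannot orient vertex normals")
  nv / len
}

# weighted tabulate: sum w over bins (bins without entries stay zero)
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, group = bin, reorder = TRUE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# one-ring neighbor list
.one_rings <- function(tr, n) {
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)],
              tr[, c(2, 1)], tr[, c(3, 2)], tr[, c(1, 3)])
  sp <- split(ed[, 2], ed[, 1])
  out <- vector("list", n)
  out[as.integer(names(sp))] <- lapply(sp, function(x) sort(unique(x)))
  out
}

#' Tangential gradient of the radius field
#'
#' Per-vertex weighted least-squares estimate of the in-surface gradient
#' of `radius`: one-ring edge vectors are projected onto the tangent plane
#' (orthogonal complement of the vertex normal) and the radius differences
#' are regressed on them. Robust on irregular meshes; boundary vertices use
#' their (partial) one-ring.
#'
#' @param surface a [medial_surface()].
#' @param values scalar field to differentiate; defaults to the radius.
#' @return n x 3 matrix of tangent-plane gradient vectors (mm/mm).
#' @keywords internal
#' @export
tangential_gradient <- function(surface, values = surface$radius) {
  v <- surface$vertices
  n <- nrow(v)
  nb <- .one_rings(surface$triangles, n)
  nrm <- surface$normals
  g <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    j <- nb[[i]]
    if (length(j) < 2L) next
    E <- v[j, , drop = FALSE] - matrix(v[i, ], length(j), 3, byrow = TRUE)
    d <- values[j] - values[i]
    ni <- nrm[i, ]
    Et <- E - outer(as.vector(E %*% ni), ni)
    # orthonormal tangent basis
    t1 <- Et[which.max(rowSums(Et^2)), ]
    l1 <- sqrt(sum(t1^2))
    if (l1 < 1e-12) next
    t1 <- t1 / l1
    t2 <- c(ni[2] * t1[3] - ni[3] * t1[2],
            ni[3] * t1[1] - ni[1] * t1[3],
            ni[1] * t1[2] - ni[2] * t1[1])
    X <- cbind(Et %*% t1, Et %*% t2)
    w <- 1 / sqrt(rowSums(E^2))
    fit <- tryCatch(.lm.fit(X * w, d * w), error = function(e) NULL)
    if (is.null(fit) || fit$rank < 2L) next
    co <- fit$coefficients
    g[i, ] <- co[1] * t1 + co[2] * t2
  }
  g
}

#' Inverse skeletonization: spoke vectors and boundary points
#'
#' Reconstructs the two tract boundary sheets from the skeleton and radius
#' field. At each vertex m with unit normal n, radius r and tangential
#' radius gradient g, the medial (Blum) boundary relation gives the two
#' unit spoke directions
#' \deqn{U_\pm = -g \pm \sqrt{1 - \|g\|^2}\, n}
#' and boundary points \eqn{b_\pm = m + r U_\pm}, each at distance exactly
#' r from the skeleton. Vertices violating medial feasibility
#' (\eqn{\|g\| > 1}) are flagged invalid and excluded downstream rather
#' than clamped; their count is reported via `attr(, "n_invalid")`.
#'
#' @param surface a [medial_surface()].
#' @return An object of class `spoke_set`: list with `U_plus`, `U_minus`
#'   (unit direction matrices), `b_plus`, `b_minus` (boundary points, mm),
#'   `grad` (tangential radius gradient), and logical `valid`.
#' @export
build_spokes <- function(surface) {
  g <- tangential_gradient(surface)
  gn2 <- rowSums(g^2)
  valid <- is.finite(gn2) & gn2 <= 1
  if (!any(valid)) stop("all vertices medially infeasible: empty spoke set")
  s <- sqrt(pmax(0, 1 - gn2))
  n <- surface$normals
  Up <- -g + n * s
  Um <- -g - n * s
  Up[!valid, ] <- NA_real_
  Um[!valid, ] <- NA_real_
  r <- surface$radius
  bp <- surface$vertices + Up * r
  bm <- surface$vertices + Um * r
  structure(list(U_plus = Up, U_minus = Um, b_plus = bp, b_minus = bm,
                 grad = g, valid = valid),
            class = "spoke_set",
            n_invalid = sum(!valid))
}

#' @export
print.spoke_set <- function(x, ...) {
  cat(sprintf("Spoke set: %d vertices (%d medially infeasible)\n",
              length(x$valid), attr(x, "n_invalid")))
  invisible(x)
}

#' Total surface area
#'
#' @param surface a [medial_surface()].
#' @return area in mm^2 (sum of triangle areas).
#' @export
surface_area <- function(surface) {
  sum(.triangle_areas(surface$vertices, surface$triangles))
}

#' Resolution elements (resels) of a smoothed surface
#'
#' The effective number of independent patches of a random field smoothed
#' with a Gaussian kernel: `area / fwhm^2`. Used by the random-field-theory
#' familywise correction.
#'
#' @param surface a [medial_surface()].
#' @param fwhm smoothing kernel full width at half maximum, mm; must be
#'   positive.
#' @export
resel_count <- function(surface, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("'fwhm' must be a positive scalar")
  surface_area(surface) / fwhm^2
}

# Cotangent-weighted Laplacian pieces: sparse symmetric weight matrix W
# with W_ij = (cot a_ij + cot b_ij)/2 (negative cotangents clamped at
# zero) and lumped vertex masses (one third of incident triangle area,
# mm^2). (W x - deg x)/mass approximates the Laplace-Beltrami operator in
# 1/mm^2, so diffusion time carries mm^2.
.mesh_laplacian <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  n <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (cn in corners) {
    a <- tr[, cn[1]]; b <- tr[, cn[2]]; cc <- tr[, cn[3]]
    # angle at a, opposite edge (b, cc)
    e1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    e2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(e1 * e2)
    cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    cr <- sqrt(rowSums(cx^2))
    cot <- pmax(dt / pmax(cr, 1e-300), 0)  # clamp obtuse contributions
    ii <- c(ii, b); jj <- c(jj, cc); ww <- c(ww, 0.5 * cot)
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  areas <- .triangle_areas(v, tr)
  mass <- numeric(n)
  for (k in 1:3)
    mass <- mass + tabulate2(tr[, k], areas / 3, n)
  list(W = W, mass = mass)
}

#' Surface heat-kernel smoothing
#'
#' Iterative discrete heat diffusion of a vertex scalar field, matched to a
#' planar Gaussian kernel of the requested FWHM: total diffusion time is
#' \eqn{\tau = \mathrm{fwhm}^2 / (16 \ln 2)}, split into explicit Euler
#' steps that satisfy the stability bound of the cotangent-weighted,
#' mass-lumped Laplace-Beltrami operator. Missing vertices (NA) are
#' excluded from the diffusion stencil, with the local mass renormalized
#' over observed neighbors, so observed values never leak into or out of
#' missing regions; the output is defined exactly where the input was.
#'
#' Smoothing preserves constants, commutes with adding a constant, and on a
#' fully observed mesh never increases the sample variance of the field.
#'
#' @param surface a [medial_surface()].
#' @param values numeric vector (length n) or matrix (n x k, k fields with
#'   a shared missingness pattern not required); NA marks missing.
#' @param fwhm kernel full width at half maximum in mm; 0 returns the
#'   input unchanged.
#' @return smoothed values, same shape as `values`.
#' @export
heat_smooth <- function(surface, values, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || is.na(fwhm) || fwhm < 0)
    stop("'fwhm' must be a non-negative scalar")
  vec <- is.null(dim(values))
  vals <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(vals) != nrow(surface$vertices))
    stop("'values' must have one entry per vertex")
  if (fwhm == 0) return(values)
  tau <- fwhm^2 / (16 * log(2))
  lap <- .mesh_laplacian(surface)

  miss <- is.na(vals)
  patterns <- apply(miss, 2, function(m) paste(which(m), collapse = ","))
  out <- vals
  for (pat in unique(patterns)) {
    cols <- which(patterns == pat)
    obs <- !miss[, cols[1]]
    if (!any(obs)) next
    out[obs, cols] <- .diffuse(lap, vals[obs, cols, drop = FALSE],
                               obs, tau)
  }
  if (vec) as.vector(out) else out
}

.diffuse <- function(lap, x, obs, tau) {
  W <- lap$W[obs, obs, drop = FALSE]
  deg_all <- Matrix::rowSums(lap$W)[obs]
  deg_obs <- Matrix::rowSums(W)
  # mass renormalization: scale lumped mass by the observed weight
  # fraction so the local averaging rate matches the fully observed mesh
  frac <- ifelse(deg_all > 0, deg_obs / deg_all, 1)
  mass <- lap$mass[obs] * pmax(frac, 1e-12)
  rate <- deg_obs / mass                  # 1/mm^2 stability scale
  if (all(rate <= 0)) return(x)           # isolated vertices stay put
  dt_max <- 1 / max(rate)
  nstep <- max(1L, ceiling(tau / (0.8 * dt_max)))
  dt <- tau / nstep
  for (s in seq_len(nstep)) {
    x <- x + dt * ((W %*% x) - deg_obs * x) / mass
    x <- as.matrix(x)
  }
  x
}
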