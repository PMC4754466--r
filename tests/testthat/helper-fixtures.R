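# shared fixtures, built in code

# spherical band patch (azimuth [0, phi_max], polar angle [th1, th2]) with
# analytic area phi_max * R^2 * (cos(th1) - cos(th2))
sphere_patch <- function(n_phi = 40, n_th = 40, R = 10,
                         phi_max = pi / 2, th1 = 0.3, th2 = 1.2) {
  phi <- seq(0, phi_max, length.out = n_phi)
  th <- seq(th1, th2, length.out = n_th)
  pp <- rep(phi, times = n_th)
  tt <- rep(th, each = n_phi)
  verts <- cbind(R * sin(tt) * cos(pp), R * sin(tt) * sin(pp), R * cos(tt))
  id <- function(i, j) (j - 1L) * n_phi + i
  i <- rep(seq_len(n_phi - 1L), times = n_th - 1L)
  j <- rep(seq_len(n_th - 1L), each = n_phi - 1L)
  tris <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  medial_surface(verts, tris, rep(1, n_phi * n_th))
}

# prolate tensor (length-6 lower order) with prescribed FA and MD and
# principal axis e
prolate6 <- function(fa, md, e = c(1, 0, 0)) {
  delta <- fa * md / sqrt(3 - 2 * fa^2)
  l1 <- md + 2 * delta
  l2 <- md - delta
  e <- e / sqrt(sum(e^2))
  D <- l2 * diag(3) + (l1 - l2) * outer(e, e)
  c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
}

# isotropic volume with given MD on a simple unit-voxel grid at origin
iso_volume <- function(dims, md = 0.7e-3, origin = c(0, 0, 0)) {
  arr <- array(0, c(dims, 6))
  arr[, , , c(1, 3, 6)] <- md
  aff <- diag(4)
  aff[1:3, 4] <- origin
  dt_volume(arr, aff)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

# empirical FWHM of a smoothed impulse along one grid line
measure_fwhm <- function(x, prof) {
  half <- max(prof) / 2
  f <- stats::approxfun(x, prof)
  above <- range(x[prof >= half])
  step <- min(diff(sort(unique(x))))
  lo <- stats::uniroot(function(z) f(z) - half,
                       c(above[1] - step, above[1]))$root
  hi <- stats::uniroot(function(z) f(z) - half,
                       c(above[2], above[2] + step))$root
  hi - lo
}
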