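test_that("spokes on a flat constant-radius sheet reduce to the normals", {
  surf <- gen_surface(nu = 12, nv = 8, extent = c(22, 14),
                      radius = list(type = "constant", r0 = 1.7))
  sp <- build_spokes(surf)
  expect_true(all(sp$valid))
  # gradient of a constant radius vanishes: U+- = +-n, b+- = m +- r n
  expect_lt(max(abs(sp$U_plus - surf$normals)), 1e-10)
  expect_lt(max(abs(sp$U_minus + surf$normals)), 1e-10)
  expect_lt(max(abs(sp$b_plus - (surf$vertices + 1.7 * surf$normals))),
            1e-9)
})

test_that("boundary points sit at distance r from the skeleton", {
  surf <- gen_surface("curved_sheet", nu = 15, nv = 9,
                      radius = list(type = "bump", r0 = 1.5, amp = 0.8,
                                    center = c(20, 10), width = 8))
  sp <- build_spokes(surf)
  for (b in list(sp$b_plus, sp$b_minus)) {
    d <- sqrt(rowSums((b[sp$valid, ] - surf$vertices[sp$valid, ])^2))
    expect_lt(max(abs(d / surf$radius[sp$valid] - 1)), 1e-10)
  }
  expect_lt(max(abs(rowSums(sp$U_plus[sp$valid, ]^2) - 1)), 1e-10)
})

test_that("spoke tilt under a linear radius gradient matches arcsin", {
  # r(x) = 1 + 0.3 x on a fine flat sheet: tangential gradient 0.3 along
  # x, so the spoke tilts away from the normal by arcsin(0.3)
  surf <- gen_surface(nu = 41, nv = 21, extent = c(20, 10),
                      radius = list(type = "linear", r0 = 1, slope = 0.3))
  sp <- build_spokes(surf)
  u <- attr(surf, "u"); v <- attr(surf, "v")
  interior <- u > 2 & u < 18 & v > 2 & v < 8
  tilt <- acos(pmin(1, abs(rowSums(sp$U_plus * surf$normals))))[interior]
  expect_lt(max(abs(tilt - asin(0.3))), 1e-6)
  # finite-difference oracle for the gradient on the same mesh
  g <- tangential_gradient(surf)
  fd <- (surf$radius[which(interior)[1] + 1] -
           surf$radius[which(interior)[1] - 1]) / (2 * 0.5)
  expect_equal(g[which(interior)[1], 1], fd, tolerance = 1e-8)
})

test_that("medial infeasibility is flagged, and fully infeasible fails", {
  surf <- gen_surface(nu = 15, nv = 9, extent = c(10, 6),
                      radius = list(type = "linear", r0 = 1, slope = 1.2))
  expect_error(build_spokes(surf), "infeasible")
})

test_that("non-manifold meshes are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0.5, 0.5, 1))
  tr <- rbind(c(1, 2, 3), c(2, 4, 3), c(1, 2, 5))  # edge 1-2 in 2 is fine
  expect_silent(medial_surface(v, tr, rep(1, 5)))
  tr_bad <- rbind(tr, c(1, 2, 4))                  # edge 1-2 in 3 triangles
  expect_error(medial_surface(v, tr_bad, rep(1, 5)), "non-manifold")
  expect_error(medial_surface(v, rbind(c(1, 2, 3), c(1, 2, 3)),
                              rep(1, 5)), "isolated|non-manifold")
  expect_error(medial_surface(v[1:4, ], rbind(c(1, 2, 3), c(1, 3, 2)),
                              c(1, 1, -1, 1)), "positive")
})

test_that("spoke construction is equivariant under rigid motion", {
  set.seed(31)
  surf <- gen_surface("curved_sheet", nu = 10, nv = 7,
                      radius = list(type = "linear", r0 = 1, slope = 0.02))
  sp <- build_spokes(surf)
  R <- random_rotation()
  tr <- c(5, -3, 11)
  v2 <- sweep(surf$vertices %*% t(R), 2, tr, "+")
  s2 <- medial_surface(v2, surf$triangles, surf$radius)
  sp2 <- build_spokes(s2)
  # normals may flip orientation as a set; compare boundary point sets
  b2 <- sweep(sp$b_plus %*% t(R), 2, tr, "+")
  ok <- sp$valid & sp2$valid
  match_either <- pmin(rowSums((sp2$b_plus[ok, ] - b2[ok, ])^2),
                       rowSums((sp2$b_minus[ok, ] - b2[ok, ])^2))
  expect_lt(max(match_either), 1e-16)
})

test_that("surface area and resel count follow planar geometry", {
  sheet <- gen_surface(nu = 11, nv = 11, extent = c(10, 10))
  expect_equal(surface_area(sheet), 100)
  expect_equal(resel_count(sheet, 10), 1)
  expect_error(resel_count(sheet, 0), "positive")
  # curved oracle: spherical band area
  patch <- sphere_patch(n_phi = 60, n_th = 60)
  analytic <- (pi / 2) * 100 * (cos(0.3) - cos(1.2))
  expect_lt(abs(surface_area(patch) / analytic - 1), 0.01)
  # arch (developable cylinder segment): area is exactly the extent
  arch <- gen_surface("arch", nu = 80, nv = 20, extent = c(40, 20))
  expect_lt(abs(surface_area(arch) / 800 - 1), 0.02)
})

test_that("heat smoothing preserves constants and the identity at fwhm 0", {
  surf <- gen_surface(nu = 13, nv = 9)
  expect_equal(heat_smooth(surf, rep(2.5, 117), 8), rep(2.5, 117),
               tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(117)
  expect_identical(heat_smooth(surf, x, 0), x)
  expect_error(heat_smooth(surf, x, -1), "non-negative")
})

test_that("smoothing reduces variance and commutes with constant shift", {
  surf <- gen_surface(nu = 16, nv = 12, extent = c(30, 24))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(16 * 12)
    v_prev <- var(x)
    for (fwhm in c(2, 4, 8, 16)) {
      v_now <- var(heat_smooth(surf, x, fwhm))
      expect_lte(v_now, v_prev + 1e-12)
      v_prev <- v_now
    }
    expect_equal(heat_smooth(surf, x + 7, 6), heat_smooth(surf, x, 6) + 7,
                 tolerance = 1e-9)
  }
})

test_that("smoothing respects missing vertices", {
  surf <- gen_surface(nu = 14, nv = 10)
  set.seed(4)
  x <- rnorm(140)
  x[sample(140, 30)] <- NA
  sm <- heat_smooth(surf, x, 8)
  expect_identical(is.na(sm), is.na(x))
  # observed-only constant stays constant despite holes in the stencil
  cst <- ifelse(is.na(x), NA_real_, 3)
  expect_equal(heat_smooth(surf, cst, 8)[!is.na(x)], rep(3, 110),
               tolerance = 1e-12)
})

test_that("an 8 mm kernel has an 8 mm empirical FWHM", {
  surf <- gen_surface(nu = 41, nv = 21, extent = c(40, 20))
  u <- attr(surf, "u"); v <- attr(surf, "v")
  ctr <- which(u == 20 & v == 10)
  imp <- replace(rep(0, 41 * 21), ctr, 1)
  sm <- heat_smooth(surf, imp, 8)
  row <- which(v == 10)
  expect_lt(abs(measure_fwhm(u[row], sm[row]) / 8 - 1), 0.1)
  col <- which(u == 20)
  expect_lt(abs(measure_fwhm(v[col], sm[col]) / 8 - 1), 0.1)
})

test_that("VTK legacy and XML round trips preserve the surface", {
  surf <- gen_surface("curved_sheet", nu = 9, nv = 6,
                      radius = list(type = "linear", r0 = 2, slope = 0.01),
                      tract_name = "CST", hemisphere = "left")
  extra <- list(fa_mean = seq(0, 1, length.out = 54),
                plateau_age = c(rep(NA, 5), seq_len(49)))
  for (ext in c("vtk", "vtp")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_surface_vtk(surf, path, arrays = extra)
    got <- read_surface_vtk(path, tract_name = "CST", hemisphere = "left")
    expect_equal(got$surface$vertices, surf$vertices, tolerance = 1e-6)
    expect_identical(got$surface$triangles, surf$triangles)
    expect_equal(got$surface$radius, surf$radius, tolerance = 1e-6)
    expect_equal(got$arrays$fa_mean, extra$fa_mean, tolerance = 1e-6)
    expect_identical(is.na(got$arrays$plateau_age), is.na(extra$plateau_age))
  }
})
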