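test_that("generated grids have the expected combinatorics and invariants", {
  surf <- gen_surface(nu = 20, nv = 10, extent = c(40, 20))
  expect_identical(nrow(surf$vertices), 200L)
  expect_identical(nrow(surf$triangles), 2L * 19L * 9L)
  expect_s3_class(surf, "medial_surface")  # constructor validates
  expect_lt(max(abs(rowSums(surf$normals^2) - 1)), 1e-12)
  expect_error(gen_surface(radius = list(type = "linear", r0 = 1,
                                         slope = -0.1)), "positive")
  expect_error(gen_surface(nu = 1), ">= 2")
})

test_that("cohorts reproduce the study composition and are seeded", {
  co <- gen_cohort(178, female_fraction = 95 / 178, seed = 7)
  expect_identical(sum(co$sex == "M"), 83L)
  expect_identical(sum(co$sex == "F"), 95L)
  expect_true(all(co$age >= 6 & co$age <= 30))
  expect_identical(co, gen_cohort(178, female_fraction = 95 / 178,
                                  seed = 7))
  expect_false(identical(co$age,
                         gen_cohort(178, female_fraction = 95 / 178,
                                    seed = 8)$age))
  # uniform-age moments: mean 18, SE = (30-6)/sqrt(12)/sqrt(n)
  big <- gen_cohort(10000, seed = 9)
  expect_lt(abs(mean(big$age) - 18), 3 * 24 / sqrt(12) / 100)
  # study preset reproduces the empirical moments
  st <- gen_cohort(20000, seed = 10, age_dist = "study")
  expect_lt(abs(mean(st$age[st$sex == "F"]) - 16.0), 0.5)
  expect_error(gen_cohort(10, age_min = 30, age_max = 6), "below")
})

test_that("growth fields honor their regional construction", {
  surf <- gen_surface(nu = 20, nv = 10)
  # single region, fixed parameters -> constant maps
  f1 <- gen_growth_field(surf, regions = list(
    list(vertices = 1:200, model = "exponential", t = 4, C = 0.55,
         delta = 0.08)), smooth_fwhm = 0, seed = 1)
  expect_equal(unique(f1$t), 4)
  expect_equal(unique(f1$C), 0.55)
  expect_equal(unique(f1$A), 0.08 / (exp(-30 / 4) - exp(-6 / 4)))
  # two regions, unsmoothed -> bimodal time constants
  f2 <- gen_growth_field(surf, regions = list(
    list(vertices = 1:100, model = "exponential", t = 3, C = 0.5,
         delta = 0.08),
    list(vertices = 101:200, model = "exponential", t = 8, C = 0.5,
         delta = 0.08)), smooth_fwhm = 0, seed = 2)
  expect_setequal(unique(f2$t), c(3, 8))
  expect_error(gen_growth_field(surf, regions = list(
    list(vertices = 1:199, model = "none", C = 0.5))), "partition")
})

test_that("sex effects shift ground-truth plateaus by ln(10) * (m - 1) * t", {
  surf <- gen_surface(nu = 10, nv = 6)
  fld <- gen_growth_field(surf, regions = list(
    list(vertices = 1:60, model = "exponential", t = c(3, 5), C = 0.55,
         delta = 0.08, sex_t_mult = 1.8)), smooth_fwhm = 0, seed = 3)
  diff <- true_plateau_age(fld, "M") - true_plateau_age(fld, "F")
  expect_equal(diff, log(10) * 0.8 * fld$t, tolerance = 1e-12)
  # plateau identity: T = age_min + t ln 10, exactly
  expect_equal(true_plateau_age(fld, "F"), 6 + fld$t * log(10))
})

test_that("measures follow the curves with calibrated noise", {
  surf <- gen_surface(nu = 10, nv = 6)
  fld0 <- gen_growth_field(surf, regions = list(
    list(vertices = 1:60, model = "exponential", t = 4, C = 0.55,
         delta = -0.2 * (exp(-30 / 4) - exp(-6 / 4)))),
    noise_sd = 0, seed = 4)
  subj <- data.frame(id = "S1", age = 6, sex = "F",
                     stringsAsFactors = FALSE)
  m0 <- gen_vertex_measures(surf, subj, field_fa = fld0, seed = 5)
  expect_equal(unname(m0$fa[1, ]), rep(0.55 - 0.2 * exp(-1.5), 60),
               tolerance = 1e-12)
  # noise calibration at n = 10000 draws
  fld <- gen_growth_field(surf, regions = list(
    list(vertices = 1:60, model = "none", C = 0.5)), seed = 6)
  co <- gen_cohort(200, seed = 7)
  mm <- gen_vertex_measures(surf, co, field_fa = fld, seed = 8)
  resid <- sweep(mm$fa, 2, growth_curve(fld, 1, "F")[1, ])
  expect_lt(abs(sd(resid) / 0.03 - 1), 0.05)
  # determinism
  mm2 <- gen_vertex_measures(surf, co, field_fa = fld, seed = 8)
  expect_identical(mm$fa, mm2$fa)
  # missingness applies to fa and md jointly
  mi <- gen_vertex_measures(surf, co, field_fa = fld, missing_rate = 0.2,
                            seed = 9)
  expect_identical(is.na(mi$fa), is.na(mi$md))
  expect_gt(mean(is.na(mi$fa)), 0.1)
})

test_that("no-age-effect vertices yield null regression slopes", {
  surf <- gen_surface(nu = 6, nv = 5)
  fld <- gen_growth_field(surf, regions = list(
    list(vertices = 1:30, model = "none", C = 0.5)), seed = 10)
  cover <- 0L
  n_try <- 20L
  for (s in seq_len(n_try)) {
    co <- gen_cohort(90, seed = 100 + s)
    mm <- gen_vertex_measures(surf, co, field_fa = fld, seed = 200 + s)
    ft <- fit_linear(co$age, mm$fa[, 1 + (s %% 30)])
    ci <- ft$a + c(-1, 1) * qt(0.975, ft$n - 2) * ft$se_a
    cover <- cover + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(cover / n_try, 0.9)
})

test_that("embedded tensor volumes round-trip through projection", {
  surf <- gen_surface(nu = 20, nv = 10, extent = c(40, 20),
                      radius = list(type = "constant", r0 = 2.5))
  f_fa <- gen_growth_field(surf, measure = "fa", seed = 11)
  f_md <- gen_growth_field(surf, measure = "md", seed = 12)
  subj <- gen_cohort(2, seed = 13)
  sp <- build_spokes(surf)
  vol <- gen_tensor_volume(surf, subj[1, ], field_fa = f_fa,
                           field_md = f_md)
  res <- sample_max_fa(surf, sp, vol)
  fa_true <- as.vector(growth_curve(f_fa, subj$age[1], subj$sex[1]))
  md_true <- as.vector(growth_curve(f_md, subj$age[1], subj$sex[1]))
  expect_lt(max(abs(res$fa - fa_true), na.rm = TRUE), 0.02)
  expect_lt(max(abs(res$md - md_true) / md_true, na.rm = TRUE), 0.02)
  expect_lt(mean(is.na(res$fa)), 0.05)
  # a background-only volume projects to nothing
  none <- gen_growth_field(surf, regions = list(
    list(vertices = 1:200, model = "none", C = 0.05)), seed = 14)
  vol0 <- gen_tensor_volume(surf, subj[1, ], field_fa = none)
  expect_true(all(is.na(sample_max_fa(surf, sp, vol0)$fa)))
})

test_that("finer voxels do not worsen the projection round trip", {
  surf <- gen_surface("arch", nu = 16, nv = 8, extent = c(30, 15),
                      radius = list(type = "constant", r0 = 2))
  f_fa <- gen_growth_field(surf, regions = list(
    list(vertices = 1:128, model = "none", C = c(0.4, 0.6))),
    smooth_fwhm = 10, seed = 15)
  subj <- data.frame(id = "S1", age = 15, sex = "F",
                     stringsAsFactors = FALSE)
  sp <- build_spokes(surf)
  fa_true <- as.vector(growth_curve(f_fa, 15, "F"))
  err <- sapply(c(1.5, 0.75), function(vs) {
    vol <- gen_tensor_volume(surf, subj, field_fa = f_fa, voxel_size = vs)
    res <- sample_max_fa(surf, sp, vol)
    mean(abs(res$fa - fa_true), na.rm = TRUE)
  })
  expect_lte(err[2], err[1] + 1e-6)
})
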