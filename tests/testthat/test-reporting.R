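make_results <- function(seed, n_subj = 120, nv = 60, t_fast = 3,
                         t_slow = 8) {
  surf <- gen_surface(nu = 10, nv = 6, extent = c(60, 30))
  fld <- gen_growth_field(surf, regions = list(
    list(vertices = 1:(nv / 2), model = "exponential", t = t_fast,
         C = 0.55, delta = 0.1),
    list(vertices = (nv / 2 + 1):nv, model = "exponential", t = t_slow,
         C = 0.55, delta = 0.1)), smooth_fwhm = 0, seed = seed)
  co <- gen_cohort(n_subj, female_fraction = 0.5, seed = seed + 1)
  mm <- gen_vertex_measures(surf, co, field_fa = fld, seed = seed + 2)
  fits <- fit_vertices(mm, measure = "fa")
  list(surf = surf, res = infer_vertices(fits, surf), meas = mm,
       fld = fld, co = co)
}

test_that("tract summaries aggregate masks correctly", {
  fx <- make_results(51)
  ts <- tract_summary(fx$res, tract = "SIM")
  expect_s3_class(ts, "tract_summary")
  expect_identical(nrow(ts), 2L)
  # percentages bounded and mutually exclusive
  expect_true(all(ts$p_exp + ts$p_lin <= 100))
  # exact identity: mean_T = age_min + ln 10 * mean_t
  expect_equal(ts$mean_T, 6 + log(10) * ts$mean_t, tolerance = 1e-12)
  expect_equal(ts$mean_se_T, log(10) * ts$mean_se_t, tolerance = 1e-12)
  # permutation invariance in vertex order
  perm <- fx$res[sample(nrow(fx$res)), ]
  class(perm) <- class(fx$res)
  attr(perm, "measure") <- "fa"
  ts2 <- tract_summary(perm, tract = "SIM")
  ts2 <- ts2[match(ts$sex, ts2$sex), ]
  expect_equal(ts$p_exp, ts2$p_exp)
  expect_equal(ts$mean_t, ts2$mean_t)
})

test_that("single-vertex tracts give all-or-nothing percentages", {
  fx <- make_results(53)
  one <- fx$res[fx$res$vertex == 1, ]
  class(one) <- class(fx$res)
  attr(one, "measure") <- "fa"
  ts <- tract_summary(one)
  expect_true(all(ts$p_exp %in% c(0, 100)))
  # empty input is flagged, not an error
  none <- fx$res[0, ]
  class(none) <- class(fx$res)
  attr(none, "measure") <- "fa"
  expect_identical(nrow(tract_summary(none)), 0L)
})

test_that("hemisphere combination pools vertices with correct weights", {
  fx <- make_results(55)
  resL <- fx$res
  # identical sides: combined summary equals either side
  comb <- combine_hemispheres(resL, resL)
  tsL <- tract_summary(resL)
  tsC <- tract_summary(comb)
  tsC <- tsC[match(tsL$sex, tsC$sex), ]
  expect_equal(tsL$p_exp, tsC$p_exp)
  expect_equal(tsL$mean_t, tsC$mean_t)
  expect_equal(tsL$mean_T, tsC$mean_T)
  # weighted-mean identity on two genuinely different sides
  fy <- make_results(57, t_fast = 4, t_slow = 6)
  comb2 <- combine_hemispheres(resL, fy$res)
  for (sx in c("M", "F")) {
    mask_l <- resL$sex == sx & resL$chosen_model == "exponential"
    mask_r <- fy$res$sex == sx & fy$res$chosen_model == "exponential"
    nl <- sum(mask_l); nr <- sum(mask_r)
    want <- (nl * mean(resL$exp_t[mask_l]) +
               nr * mean(fy$res$exp_t[mask_r])) / (nl + nr)
    got <- tract_summary(comb2)
    expect_equal(got$mean_t[got$sex == sx], want, tolerance = 1e-12)
  }
  bad <- fy$res
  attr(bad, "measure") <- "md"
  expect_error(combine_hemispheres(resL, bad), "measure")
})

test_that("mean trajectories recover the generating curve", {
  surf <- gen_surface(nu = 8, nv = 5)
  fld <- gen_growth_field(surf, regions = list(
    list(vertices = 1:40, model = "exponential", t = 4, C = 0.55,
         delta = 0.1)), smooth_fwhm = 0, noise_sd = 0, seed = 59)
  co <- gen_cohort(80, female_fraction = 1, seed = 60)
  mm <- gen_vertex_measures(surf, co, field_fa = fld, seed = 61)
  tr <- mean_trajectory(mm, mask = 1:40, measure = "fa")
  # identical noiseless vertices: subject means lie on the curve exactly
  want <- as.vector(growth_curve(fld, co$age, "F", vertices = 1))
  expect_equal(tr$series$mean_value, want, tolerance = 1e-12)
  expect_equal(tr$fits$F$t, 4, tolerance = 1e-4)
  expect_equal(tr$fits$F$plateau$T, 6 + 4 * log(10), tolerance = 1e-3)
  # noisy group fit still recovers the common time constant
  fld2 <- gen_growth_field(surf, regions = list(
    list(vertices = 1:40, model = "exponential", t = 4, C = 0.55,
         delta = 0.1)), smooth_fwhm = 0, seed = 62)
  mm2 <- gen_vertex_measures(surf, co, field_fa = fld2, seed = 63)
  tr2 <- mean_trajectory(mm2, mask = 1:40, measure = "fa")
  expect_equal(tr2$fits$F$t, 4, tolerance = 0.25)
  # shift equivariance: constant offset moves C, leaves t alone
  mm3 <- mm2
  mm3$fa <- mm3$fa + 0.1
  tr3 <- mean_trajectory(mm3, mask = 1:40, measure = "fa")
  expect_equal(tr3$fits$F$t, tr2$fits$F$t, tolerance = 1e-6)
  expect_equal(tr3$fits$F$C, tr2$fits$F$C + 0.1, tolerance = 1e-6)
  # empty mask is explicit
  expect_true(mean_trajectory(mm2, integer(0))$empty)
})

test_that("fast and slow patches are ordered correctly end to end", {
  for (seed in c(71, 73, 75)) {
    fx <- make_results(seed)
    for (sx in c("M", "F")) {
      rr <- fx$res[fx$res$sex == sx, ]
      fast <- rr$chosen_model == "exponential" & rr$vertex <= 30
      slow <- rr$chosen_model == "exponential" & rr$vertex > 30
      expect_gt(mean(rr$T[slow]), mean(rr$T[fast]))
    }
  }
})

test_that("half-away-from-zero rounding is deterministic", {
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(-0.5), -1)
  expect_identical(round_half_up(2.25, 1), 2.3)
  expect_identical(round_half_up(26.93), 27)
  expect_identical(round_half_up(12.45, 1), 12.5)  # round() would give 12.4
})

test_that("the full pipeline object prints, summarizes and exports", {
  surf <- gen_surface(nu = 10, nv = 6, extent = c(60, 30))
  fld <- gen_growth_field(surf, seed = 77)
  co <- gen_cohort(100, seed = 78)
  mm <- gen_vertex_measures(surf, co, field_fa = fld, seed = 79)
  tm <- tract_maturation(mm, surf, fwhm = 8)
  expect_s3_class(tm, "tract_maturation")
  expect_output(print(tm), "Tract maturation")
  expect_s3_class(summary(tm), "tract_summary")
  path <- withr::local_tempfile(fileext = ".vtk")
  write_maturation_vtk(tm, path)
  got <- read_surface_vtk(path)
  expect_true(all(c("rate_F", "plateau_age_F", "sig_model_F") %in%
                    names(got$arrays)))
  # NaN codes non-significant vertices in the exported maps
  resF <- tm$results[tm$results$sex == "F", ]
  resF <- resF[order(resF$vertex), ]
  expect_identical(is.na(got$arrays$plateau_age_F),
                   resF$chosen_model != "exponential")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(tm))
})
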