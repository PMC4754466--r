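#' Random-field-theory familywise threshold on a surface
#'
#' Vertexwise p values are Gaussianized (p -> z) and the peak-level
#' familywise threshold z* solves `E[EC](z) = alpha`, where the expected
#' Euler characteristic of the suprathreshold set of a smooth unit
#' Gaussian field on the surface is
#' \deqn{E[EC](z) = P(Z > z) + R_2 \frac{4\ln 2}{(2\pi)^{3/2}} z
#'   e^{-z^2/2},}
#' with \eqn{R_2} = area / fwhm^2 resels. Gaussian EC densities are used
#' for statistic maps of any origin (the p map is z-transformed first);
#' the 1-dimensional boundary resel term is omitted. Resels use the
#' nominal applied smoothing FWHM by default; pass a residual-estimated
#' FWHM to override.
#'
#' @param surface a [medial_surface()].
#' @param fwhm smoothness of the statistic map, mm.
#' @param alpha familywise error level in (0, 1) (default 0.01).
#' @return the critical z threshold z*.
#' @seealso [resel_count()]
#' @export
rft_threshold <- function(surface, fwhm, alpha = 0.01) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  r2 <- resel_count(surface, fwhm)
  expected_ec <- function(z)
    stats::pnorm(z, lower.tail = FALSE) +
    r2 * (4 * log(2)) / (2 * pi)^1.5 * z * exp(-z^2 / 2)
  # E[EC] decreases in z beyond z = 1; bracket the root there
  f <- function(z) expected_ec(z) - alpha
  if (f(1) < 0) return(stats::uniroot(f, c(0, 1), tol = 1e-12)$root)
  stats::uniroot(f, c(1, 50), tol = 1e-12)$root
}

p_to_z <- function(p) stats::qnorm(p, lower.tail = FALSE)

#' Model selection at one vertex
#'
#' Applies the selection rule: if both the linear and exponential fits
#' survive the familywise correction, the smaller AIC wins; if exactly
#' one survives, it is chosen; otherwise no model. A direction filter
#' then discards vertices whose fitted trend runs against maturation
#' (for FA only increases are kept: A < 0 exponential, slope > 0 linear;
#' for MD only decreases: A > 0, slope < 0) -- reversed trends do not
#' survive correction in practice and are excluded from the maturation
#' maps. A non-converged exponential fit is never selected.
#'
#' @param lin,exp_ fits from [fit_linear()] / [fit_exponential()] at the
#'   same vertex, sex and measure (either may be NULL).
#' @param rft_lin,rft_exp logical: does each model survive the corrected
#'   threshold?
#' @param measure "fa" or "md" (sets the direction filter).
#' @return list with `chosen_model` ("exponential", "linear" or "none")
#'   and `direction_ok`.
#' @export
select_model <- function(lin, exp_, rft_lin, rft_exp,
                         measure = c("fa", "md")) {
  measure <- match.arg(measure)
  ok_exp <- isTRUE(rft_exp) && !is.null(exp_) && isTRUE(exp_$converged)
  ok_lin <- isTRUE(rft_lin) && !is.null(lin)
  chosen <- if (ok_exp && ok_lin) {
    if (exp_$aic < lin$aic) "exponential" else "linear"
  } else if (ok_exp) "exponential" else if (ok_lin) "linear" else "none"
  dir_ok <- TRUE
  if (chosen == "exponential") {
    dir_ok <- if (measure == "fa") exp_$A < 0 else exp_$A > 0
  } else if (chosen == "linear") {
    dir_ok <- if (measure == "fa") lin$a > 0 else lin$a < 0
  }
  if (!dir_ok) chosen <- "none"
  list(chosen_model = chosen, direction_ok = dir_ok)
}

#' Plateau age of an exponential maturation curve
#'
#' The age at which the measure has completed 90 percent of its remaining
#' change from `age_min` toward the asymptote:
#' \deqn{T = \mathrm{age}_{min} + t \ln 10,}
#' since \eqn{e^{-(T - \mathrm{age}_{min})/t} = 0.1}. The standard error
#' propagates exactly through the linear map: `se_T = ln(10) * se_t`.
#' `valid_window` flags plateaus inside the modeled window
#' (T <= age_max).
#'
#' @param fit an [fit_exponential()] result, or a numeric vector of time
#'   constants t (years).
#' @param se_t standard error(s) of t (taken from `fit` when omitted).
#' @param age_min,age_max the modeled age window, years.
#' @return list of class `maturation_estimate` with vectors `T`, `se_T`,
#'   `valid_window`.
#' @export
plateau_age <- function(fit, se_t = NULL, age_min = 6, age_max = 30) {
  if (inherits(fit, "exp_fit")) {
    if (!isTRUE(fit$converged)) stop("no plateau for a non-converged fit")
    t <- fit$t
    if (is.null(se_t)) se_t <- fit$se_t
  } else {
    t <- as.numeric(fit)
  }
  if (any(t <= 0, na.rm = TRUE)) stop("time constants must be positive")
  T_ <- age_min + t * log(10)
  se_T <- if (is.null(se_t)) rep(NA_real_, length(T_)) else
    log(10) * as.numeric(se_t)
  structure(list(T = T_, se_T = se_T, valid_window = T_ <= age_max),
            class = "maturation_estimate")
}

#' @export
print.maturation_estimate <- function(x, ...) {
  cat(sprintf("Plateau age: %s years\n",
              paste(sprintf("%.1f +/- %.1f", x$T, x$se_T),
                    collapse = ", ")))
  invisible(x)
}

#' Yearly rate of change up to the plateau
#'
#' For the exponential model, the absolute change per year from `age_min`
#' to the plateau age T:
#' \deqn{\mathrm{rate} = \frac{|y(T) - y(\mathrm{age}_{min})|}{T -
#'   \mathrm{age}_{min}} = \frac{0.9\,|A|\,e^{-\mathrm{age}_{min}/t}}{t
#'   \ln 10}.}
#' For the linear model the rate is simply `|a|`.
#'
#' @param fit an [fit_exponential()] result, or numeric A (with `t`).
#' @param t time constant(s), years, when `fit` is numeric.
#' @param age_min start of the modeled window, years.
#' @export
rate_exponential <- function(fit, t = NULL, age_min = 6) {
  if (inherits(fit, "exp_fit")) {
    A <- fit$A; t <- fit$t
  } else A <- as.numeric(fit)
  if (any(t <= 0, na.rm = TRUE)) stop("time constants must be positive")
  0.9 * abs(A) * exp(-age_min / t) / (t * log(10))
}

#' @rdname rate_exponential
#' @param a linear slope(s), units/year.
#' @export
rate_linear <- function(fit, a = NULL) {
  if (inherits(fit, "lin_fit")) a <- fit$a
  else if (is.null(a)) a <- as.numeric(fit)
  abs(a)
}

#' Between-sex comparison of plateau ages by interval overlap
#'
#' Two plateau estimates differ significantly when their one-standard-
#' error intervals `[T - se, T + se]` are disjoint; overlapping intervals
#' are not considered different. Also reports which sex plateaus earlier.
#'
#' @param T_f,se_f,T_m,se_m female and male plateau ages and standard
#'   errors, years (vectorized).
#' @return data.frame with `significant`, `earlier` ("F", "M" or NA when
#'   not significant), and `comparable` (FALSE where either estimate is
#'   missing).
#' @export
sex_overlap_test <- function(T_f, se_f, T_m, se_m) {
  comparable <- is.finite(T_f) & is.finite(se_f) &
    is.finite(T_m) & is.finite(se_m)
  disjoint <- (T_f + se_f < T_m - se_m) | (T_m + se_m < T_f - se_f)
  sig <- comparable & disjoint
  earlier <- ifelse(sig, ifelse(T_f < T_m, "F", "M"), NA_character_)
  data.frame(significant = ifelse(comparable, sig, NA),
             earlier = earlier, comparable = comparable,
             stringsAsFactors = FALSE)
}

#' Vertexwise inference and maturation maps
#'
#' Takes the per-vertex fit table, applies the F tests' random-field
#' correction per model, selects the winning model per vertex (AIC where
#' both survive), applies the direction filter, and computes plateau
#' ages, their standard errors and yearly rates for the selected
#' vertices.
#'
#' @param fits a [fit_vertices()] table.
#' @param surface the surface the fits live on.
#' @param fwhm smoothing FWHM used on the measures, mm.
#' @param alpha corrected familywise level (default 0.01).
#' @param age_min,age_max modeled age window, years.
#' @return data.frame of class `vertex_results`: per (vertex, sex) the
#'   chosen model, significance flags, `T`, `se_T`, `rate` and carrying
#'   the fit columns; attribute `z_star` stores the threshold.
#' @export
infer_vertices <- function(fits, surface, fwhm = 8, alpha = 0.01,
                           age_min = 6, age_max = 30) {
  measure <- attr(fits, "measure")
  z_star <- rft_threshold(surface, fwhm, alpha)
  z_lin <- p_to_z(pmin(pmax(fits$lin_p, 1e-300), 1))
  z_exp <- p_to_z(pmin(pmax(fits$exp_p, 1e-300), 1))
  rft_lin <- !is.na(z_lin) & z_lin >= z_star
  rft_exp <- !is.na(z_exp) & z_exp >= z_star
  n <- nrow(fits)
  chosen <- character(n)
  for (i in seq_len(n)) {
    lin <- if (is.na(fits$lin_a[i])) NULL else
      list(a = fits$lin_a[i], aic = fits$lin_aic[i])
    ex <- if (is.na(fits$exp_t[i])) NULL else
      list(A = fits$exp_A[i], aic = fits$exp_aic[i],
           converged = isTRUE(fits$exp_converged[i]))
    if (!is.null(lin)) class(lin) <- c("lin_fit", "growth_fit")
    if (!is.null(ex)) class(ex) <- c("exp_fit", "growth_fit")
    sel <- select_model(lin, ex, rft_lin[i], rft_exp[i], measure)
    chosen[i] <- sel$chosen_model
  }
  T_ <- se_T <- rate <- rep(NA_real_, n)
  ie <- chosen == "exponential"
  if (any(ie)) {
    pa <- plateau_age(fits$exp_t[ie], fits$exp_se_t[ie],
                      age_min = age_min, age_max = age_max)
    T_[ie] <- pa$T
    se_T[ie] <- pa$se_T
    rate[ie] <- rate_exponential(fits$exp_A[ie], t = fits$exp_t[ie],
                                 age_min = age_min)
  }
  il <- chosen == "linear"
  rate[il] <- rate_linear(fits$lin_a[il])
  out <- cbind(fits,
               data.frame(chosen_model = chosen, rft_lin = rft_lin,
                          rft_exp = rft_exp, T = T_, se_T = se_T,
                          rate = rate, stringsAsFactors = FALSE))
  class(out) <- c("vertex_results", "data.frame")
  attr(out, "measure") <- measure
  attr(out, "z_star") <- z_star
  attr(out, "age_min") <- age_min
  attr(out, "age_max") <- age_max
  out
}

#' Tract-specific maturation analysis (full pipeline)
#'
#' One call from projected (or generated) vertex measures to maturation
#' maps and a tract summary: surface smoothing of the per-subject maps,
#' sex-stratified vertexwise fits of both age models, random-field
#' corrected F tests, AIC model selection with direction filtering,
#' plateau ages and rates, and tract-level aggregates with the
#' between-sex overlap comparison.
#'
#' @param measures a [vertex_measures()] set (unsmoothed).
#' @param surface the matching [medial_surface()].
#' @param measure "fa" or "md".
#' @param fwhm surface smoothing FWHM, mm (8 by default; 0 skips
#'   smoothing).
#' @param rft_fwhm smoothness assumed by the familywise correction;
#'   defaults to `fwhm` (or 8 mm when smoothing is skipped, since the
#'   resel count is undefined at zero smoothness).
#' @param alpha corrected familywise level.
#' @param age_min,age_max modeled age window, years.
#' @param ... passed to [fit_exponential()].
#' @return object of class `tract_maturation`: `results` (per-vertex),
#'   `summary` (per-sex [tract_summary()]), `sex_comparison`, the
#'   smoothed `measures` and the call parameters.
#' @examples
#' surf <- gen_surface(nu = 12, nv = 6)
#' field <- gen_growth_field(surf, seed = 1)
#' cohort <- gen_cohort(60, seed = 2)
#' meas <- gen_vertex_measures(surf, cohort, field_fa = field, seed = 3)
#' fitg <- tract_maturation(meas, surf, fwhm = 0)
#' print(fitg)
#' @export
tract_maturation <- function(measures, surface, measure = c("fa", "md"),
                             fwhm = 8, rft_fwhm = NULL, alpha = 0.01,
                             age_min = 6, age_max = 30, ...) {
  measure <- match.arg(measure)
  if (is.null(rft_fwhm)) rft_fwhm <- if (fwhm > 0) fwhm else 8
  sm <- if (fwhm > 0) smooth_measures(measures, surface, fwhm) else
    measures
  fits <- fit_vertices(sm, measure = measure, ...)
  res <- infer_vertices(fits, surface, fwhm = rft_fwhm, alpha = alpha,
                        age_min = age_min, age_max = age_max)
  summ <- tract_summary(res, tract = surface$tract_name,
                        age_min = age_min)
  structure(list(results = res, summary = summ,
                 measures = sm, surface = surface,
                 params = list(measure = measure, fwhm = fwhm,
                               alpha = alpha, age_min = age_min,
                               age_max = age_max)),
            class = "tract_maturation")
}

#' @export
print.tract_maturation <- function(x, ...) {
  p <- x$params
  cat(sprintf("Tract maturation analysis: %s, %s\n",
              x$surface$tract_name, toupper(p$measure)))
  cat(sprintf("  %d vertices, smoothing %g mm, corrected alpha %g (z* = %.2f)\n",
              nrow(x$surface$vertices), p$fwhm, p$alpha,
              attr(x$results, "z_star")))
  print(x$summary)
  invisible(x)
}

#' @export
summary.tract_maturation <- function(object, ...) object$summary

#' @export
plot.tract_maturation <- function(x, sex = c("F", "M"), ...) {
  res <- x$results
  meas <- x$measures[[x$params$measure]]
  cols <- c(F = "red3", M = "royalblue3")
  first <- TRUE
  for (sx in sex) {
    mask <- res$vertex[res$sex == sx & res$chosen_model == "exponential"]
    if (!length(mask)) next
    subj <- x$measures$subjects
    rows <- subj$sex == sx
    mu <- rowMeans(meas[rows, mask, drop = FALSE], na.rm = TRUE)
    if (first) {
      graphics::plot(subj$age[rows], mu, col = cols[sx], pch = 16,
                     xlab = "age (years)",
                     ylab = sprintf("mean %s over exponential vertices",
                                    toupper(x$params$measure)), ...)
      first <- FALSE
    } else graphics::points(subj$age[rows], mu, col = cols[sx], pch = 16)
    ft <- tryCatch(fit_exponential(subj$age[rows], mu),
                   tractmat_unfittable = function(e) NULL)
    if (!is.null(ft)) {
      aa <- seq(x$params$age_min, x$params$age_max, length.out = 100)
      graphics::lines(aa, predict(ft, aa), col = cols[sx], lwd = 2)
    }
  }
  invisible(x)
}

#' Export maturation maps as VTK point arrays
#'
#' Writes one array per quantity ("fa_mean" or "md_mean", "rate",
#' "plateau_age", "sig_model") per sex, with NaN coding non-significant
#' vertices (rendered gray by VTK viewers). `sig_model` codes none = 0,
#' linear = 1, exponential = 2.
#'
#' @param fit a [tract_maturation()] result.
#' @param path output `.vtk` or `.vtp` file.
#' @export
write_maturation_vtk <- function(fit, path) {
  res <- fit$results
  meas <- fit$measures[[fit$params$measure]]
  arrays <- list()
  nv <- nrow(fit$surface$vertices)
  for (sx in unique(res$sex)) {
    rr <- res[res$sex == sx, ]
    rr <- rr[order(rr$vertex), ]
    sig <- rr$chosen_model != "none"
    is_exp <- rr$chosen_model == "exponential"
    code <- match(rr$chosen_model, c("none", "linear", "exponential")) - 1
    pref <- function(nm) sprintf("%s_%s", nm, sx)
    arrays[[pref(paste0(fit$params$measure, "_mean"))]] <-
      colMeans(meas[fit$measures$subjects$sex == sx, , drop = FALSE],
               na.rm = TRUE)
    arrays[[pref("rate")]] <- ifelse(sig, rr$rate, NaN)
    arrays[[pref("plateau_age")]] <- ifelse(is_exp, rr$T, NaN)
    arrays[[pref("sig_model")]] <- code
  }
  write_surface_vtk(fit$surface, path, arrays = arrays)
}
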