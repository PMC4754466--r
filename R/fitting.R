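#' Vertexwise age-trajectory models
#'
#' Two candidate mean models are fitted to a vertex's measure-versus-age
#' data within each sex group:
#' \itemize{
#'   \item linear: \eqn{y = b + a\,\mathrm{age}}
#'   \item exponential: \eqn{y = C + A e^{-\mathrm{age}/t}}, with asymptote
#'     C, amplitude A (negative for increasing FA, positive for decreasing
#'     MD) and time constant t in years.
#' }
#' Each fit carries its residual sum of squares, a goodness-of-fit
#' correlation, an F test against the constant-mean null, and an AIC for
#' between-model comparison.
#'
#' `fit_linear` is ordinary least squares. `fit_exponential` exploits the
#' model's conditional linearity: given t, (C, A) solve a linear least
#' squares problem, so the profile SSE over t is minimized globally on a
#' grid (t = 0.5, 1.0, ..., 50 by default) and then polished by local
#' golden-section refinement to a relative SSE tolerance of 1e-10, with t
#' bounded in (0, 1000]. Refinement that runs into the upper bound (the
#' straight-line limit of the model) or fails to meet tolerance within 500
#' iterations sets `converged = FALSE`; such vertices fall back to the
#' linear model downstream. Standard errors come from the Gauss-Newton
#' covariance `sse/(n-3) * solve(t(J) %*% J)`.
#'
#' Fewer than 3 (linear) or 4 (exponential) complete observations, or a
#' degenerate design, signal a condition of class `tractmat_unfittable`.
#'
#' @param age numeric vector of ages, years.
#' @param y measure values (FA, or MD in mm^2/s); NA pairs are dropped.
#' @param t_grid time-constant grid for the global profile search, years.
#' @param t_max upper bound on t, years.
#' @param tol relative SSE convergence tolerance of the refinement.
#' @param max_iter refinement iteration cap.
#' @return An object of class `c("lin_fit"/"exp_fit", "growth_fit")`.
#'   Linear: `b`, `a`, `se_b`, `se_a`. Exponential: `C`, `A`, `t`,
#'   `se_C`, `se_A`, `se_t`, `converged`. Both: `sse`, `sst`, `r`,
#'   `f_stat`, `p_value`, `aic`, `n`, `model`.
#' @examples
#' age <- seq(6, 30, length.out = 25)
#' fit <- fit_exponential(age, 0.55 - 0.2 * exp(-age / 4))
#' coef(fit)
#' @export
fit_linear <- function(age, y) {
  d <- .complete_xy(age, y, 3L)
  n <- d$n
  if (stats::var(d$age) == 0)
    stop(.unfittable("zero age variance: degenerate design"))
  X <- cbind(1, d$age)
  fit <- .lm.fit(X, d$y)
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  sse <- sum(fit$residuals^2)
  sst <- sum((d$y - mean(d$y))^2)
  sig2 <- sse / (n - 2)
  cv <- sig2 * chol2inv(chol(crossprod(X)))
  ft <- f_test(sse, sst, 2L, n)
  structure(list(b = b, a = a, se_b = sqrt(cv[1, 1]), se_a = sqrt(cv[2, 2]),
                 sse = sse, sst = sst,
                 r = sign(a) * sqrt(max(0, 1 - sse / max(sst, 1e-300))),
                 f_stat = ft$f_stat, p_value = ft$p_value,
                 aic = aic_sse(sse, n, 2L), n = n, model = "linear"),
            class = c("lin_fit", "growth_fit"))
}

#' @rdname fit_linear
#' @export
fit_exponential <- function(age, y, t_grid = seq(0.5, 50, by = 0.5),
                            t_max = 1000, tol = 1e-10, max_iter = 500L) {
  d <- .complete_xy(age, y, 4L)
  n <- d$n
  if (stats::var(d$age) == 0)
    stop(.unfittable("zero age variance: degenerate design"))
  prof <- function(t) {
    X <- cbind(1, exp(-d$age / t))
    ft <- tryCatch(.lm.fit(X, d$y), error = function(e) NULL)
    if (is.null(ft) || ft$rank < 2L) return(Inf)
    sum(ft$residuals^2)
  }
  sses <- vapply(t_grid, prof, 0)
  if (all(!is.finite(sses)))
    stop(.unfittable("singular conditional system"))
  ib <- which.min(sses)
  step <- if (length(t_grid) > 1) diff(t_grid[1:2]) else 1
  lo <- max(t_grid[ib] - step, 1e-2)
  hi <- if (ib == length(t_grid)) t_max else t_grid[ib] + step

  # golden-section polish of the profile SSE
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- prof(x1); f2 <- prof(x2)
  prev <- min(f1, f2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (f1 > f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- prof(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- prof(x1)
    }
    cur <- min(f1, f2)
    if (is.finite(prev) && prev > 0 &&
        abs(prev - cur) <= tol * prev && (hi - lo) < 1e-6 * max(1, hi)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  t_hat <- if (f1 < f2) x1 else x2
  if (t_hat >= t_max * (1 - 1e-3)) converged <- FALSE

  E <- exp(-d$age / t_hat)
  X <- cbind(1, E)
  ft <- .lm.fit(X, d$y)
  C <- ft$coefficients[1]; A <- ft$coefficients[2]
  sse <- sum(ft$residuals^2)
  sst <- sum((d$y - mean(d$y))^2)
  J <- cbind(1, E, A * E * d$age / t_hat^2)
  cv <- tryCatch(chol2inv(chol(crossprod(J))) * sse / (n - 3),
                 error = function(e) matrix(NA_real_, 3, 3))
  ftt <- f_test(sse, sst, 3L, n)
  structure(list(C = C, A = A, t = t_hat,
                 se_C = sqrt(cv[1, 1]), se_A = sqrt(cv[2, 2]),
                 se_t = sqrt(cv[3, 3]),
                 sse = sse, sst = sst,
                 r = sqrt(max(0, 1 - sse / max(sst, 1e-300))),
                 f_stat = ftt$f_stat, p_value = ftt$p_value,
                 aic = aic_sse(sse, n, 3L), n = n,
                 converged = converged, model = "exponential"),
            class = c("exp_fit", "growth_fit"))
}

.complete_xy <- function(age, y, n_min) {
  if (length(age) != length(y)) stop("'age' and 'y' lengths differ")
  keep <- is.finite(age) & is.finite(y)
  if (sum(keep) < n_min)
    stop(.unfittable(sprintf("fewer than %d complete observations", n_min)))
  list(age = age[keep], y = y[keep], n = sum(keep))
}

.unfittable <- function(msg) {
  structure(class = c("tractmat_unfittable", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' F test of a mean model against the constant-mean null
#'
#' \deqn{F = \frac{(SST - SSE)/(k - 1)}{SSE/(n - k)}}
#' with p from the F distribution on (k - 1, n - k) degrees of freedom,
#' where k counts the mean parameters (2 linear, 3 exponential). A flat
#' response (SST = 0) returns p = 1 by convention; a perfect fit returns
#' p = 0.
#'
#' @param sse_model residual sum of squares of the fitted model.
#' @param sst total sum of squares about the mean.
#' @param n_params number of mean parameters k.
#' @param n number of observations (> n_params).
#' @return list with `f_stat` and `p_value`.
#' @export
f_test <- function(sse_model, sst, n_params, n) {
  if (n <= n_params) stop("n must exceed the number of parameters")
  if (sst <= 0) return(list(f_stat = 0, p_value = 1))
  if (sse_model <= 0) return(list(f_stat = Inf, p_value = 0))
  f <- ((sst - sse_model) / (n_params - 1)) / (sse_model / (n - n_params))
  f <- max(f, 0)
  list(f_stat = f,
       p_value = stats::pf(f, n_params - 1, n - n_params,
                           lower.tail = FALSE))
}

#' Akaike information criterion from a residual sum of squares
#'
#' Gaussian-likelihood AIC, counting the noise variance as a parameter:
#' `n * log(sse/n) + 2 * (k_mean_params + 1)` (so k = 3 for the linear
#' model, k = 4 for the exponential). A zero SSE maps to -Inf, which
#' still compares correctly. AIC, not AICc: at the group sizes this
#' package targets (around 90) the small-sample correction is negligible.
#'
#' @param sse residual sum of squares.
#' @param n number of observations.
#' @param k_mean_params number of mean parameters.
#' @export
aic_sse <- function(sse, n, k_mean_params) {
  if (n <= 0) stop("n must be positive")
  if (sse < 0) stop("sse must be non-negative")
  if (sse == 0) return(-Inf)
  n * log(sse / n) + 2 * (k_mean_params + 1)
}

# ---- growth_fit methods -------------------------------------------------

#' @export
print.growth_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf("Linear age trajectory: y = %.4g + %.4g * age  (n = %d)\n",
                x$b, x$a, x$n))
  } else {
    cat(sprintf(
      "Exponential age trajectory: y = %.4g + %.4g * exp(-age/%.3g)  (n = %d%s)\n",
      x$C, x$A, x$t, x$n,
      if (isTRUE(x$converged)) "" else ", not converged"))
  }
  cat(sprintf("  r = %.3f, F = %.3g (p = %.3g), AIC = %.2f\n",
              x$r, x$f_stat, x$p_value, x$aic))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  if (object$model == "linear") c(b = object$b, a = object$a)
  else c(C = object$C, A = object$A, t = object$t)
}

#' @export
predict.growth_fit <- function(object, newdata, ...) {
  age <- if (is.data.frame(newdata)) newdata$age else newdata
  if (object$model == "linear") object$b + object$a * age
  else object$C + object$A * exp(-age / object$t)
}

#' @export
summary.growth_fit <- function(object, ...) {
  est <- coef(object)
  se <- if (object$model == "linear")
    c(object$se_b, object$se_a)
  else c(object$se_C, object$se_A, object$se_t)
  tab <- cbind(Estimate = est, `Std. Error` = se)
  out <- list(model = object$model, coefficients = tab, r = object$r,
              f_stat = object$f_stat, p_value = object$p_value,
              aic = object$aic, n = object$n,
              sigma = sqrt(object$sse /
                             (object$n - length(est))))
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat(sprintf("%s age-trajectory fit (n = %d)\n", x$model, x$n))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("residual SD %.4g, r = %.3f, F = %.3g (p = %.3g), AIC = %.2f\n",
              x$sigma, x$r, x$f_stat, x$p_value, x$aic))
  invisible(x)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  # residuals were not stored to keep per-vertex objects light; refit
  # from the data if supplied
  dots <- list(...)
  if (!is.null(dots$age) && !is.null(dots$y))
    return(dots$y - predict(object, dots$age))
  stop("supply age = , y = to recompute residuals")
}

#' @export
plot.growth_fit <- function(x, age = NULL, y = NULL, ...) {
  rng <- if (is.null(age)) c(6, 30) else range(age)
  aa <- seq(rng[1], rng[2], length.out = 200)
  if (!is.null(age)) {
    graphics::plot(age, y, xlab = "age (years)", ylab = "measure", ...)
    graphics::lines(aa, predict(x, aa), col = 2, lwd = 2)
  } else {
    graphics::plot(aa, predict(x, aa), type = "l", col = 2, lwd = 2,
                   xlab = "age (years)", ylab = "measure", ...)
  }
  invisible(x)
}

#' Fit both models at every vertex, stratified by sex
#'
#' Male and female groups are fitted independently at every vertex.
#' Missing subjects are dropped listwise per vertex; vertices retaining
#' fewer than 80 percent of their group are flagged (`low_n`).
#'
#' @param measures a [vertex_measures()] (smoothed per the pipeline).
#' @param measure "fa" or "md".
#' @param sexes which groups to fit.
#' @param ... passed to [fit_exponential()].
#' @return data.frame of class `vertex_fits`, one row per
#'   (vertex, sex): linear and exponential parameters, SEs, SSE, r, F, p,
#'   AIC, convergence and n. Unfittable vertices carry NA rows.
#' @export
fit_vertices <- function(measures, measure = c("fa", "md"),
                         sexes = c("M", "F"), ...) {
  measure <- match.arg(measure)
  vals <- measures[[measure]]
  subjects <- measures$subjects
  nv <- ncol(vals)
  rows <- vector("list", length(sexes) * nv)
  k <- 0L
  for (sx in sexes) {
    grp <- which(subjects$sex == sx)
    age <- subjects$age[grp]
    gsize <- length(grp)
    for (vtx in seq_len(nv)) {
      y <- vals[grp, vtx]
      n_ok <- sum(is.finite(y))
      lin <- tryCatch(fit_linear(age, y),
                      tractmat_unfittable = function(e) NULL)
      ex <- tryCatch(fit_exponential(age, y, ...),
                     tractmat_unfittable = function(e) NULL)
      k <- k + 1L
      rows[[k]] <- data.frame(
        vertex = vtx, sex = sx, measure = measure, n = n_ok,
        low_n = n_ok < 0.8 * gsize,
        lin_b = .nav(lin$b), lin_a = .nav(lin$a),
        lin_se_a = .nav(lin$se_a), lin_sse = .nav(lin$sse),
        lin_r = .nav(lin$r), lin_f = .nav(lin$f_stat),
        lin_p = .nav(lin$p_value), lin_aic = .nav(lin$aic),
        exp_C = .nav(ex$C), exp_A = .nav(ex$A), exp_t = .nav(ex$t),
        exp_se_C = .nav(ex$se_C), exp_se_A = .nav(ex$se_A),
        exp_se_t = .nav(ex$se_t), exp_sse = .nav(ex$sse),
        exp_r = .nav(ex$r), exp_f = .nav(ex$f_stat),
        exp_p = .nav(ex$p_value), exp_aic = .nav(ex$aic),
        exp_converged = if (is.null(ex)) NA else ex$converged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vertex_fits", "data.frame")
  attr(out, "measure") <- measure
  out
}

.nav <- function(x) if (is.null(x)) NA_real_ else x
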