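# Synthetic cohorts: surfaces, growth fields, subjects, vertex measures
# and embedded tensor volumes with the statistical structure the analysis
# assumes. Every generator is a pure function of (parameters, seed).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

# moments of N(mu, sg) truncated to [lo, hi]
.trunc_norm_moments <- function(mu, sg, lo, hi) {
  a <- (lo - mu) / sg
  b <- (hi - mu) / sg
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m1 <- mu + sg * (da - db) / Z
  v <- sg^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(m1, sqrt(v))
}

# invert the truncation: underlying (mu, sg) whose truncated moments hit
# the requested targets
.trunc_norm_match <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mm <- .trunc_norm_moments(p[1], exp(p[2]), lo, hi)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  p <- stats::optim(c(target_mean, log(target_sd)), obj)$par
  c(p[1], exp(p[2]))
}

#' Generate a test-fixture medial surface
#'
#' Deterministic structured meshes standing in for template tract
#' surfaces: a flat sheet, a gently curved (sinusoidal) sheet, or an arch
#' (cylinder segment, whose developable geometry gives an exact analytic
#' area `extent[1] * extent[2]`). The grid is triangulated consistently
#' (two triangles per cell) and carries a radius field.
#'
#' @param kind "flat_sheet", "curved_sheet" or "arch".
#' @param nu,nv grid resolution (vertices per side, >= 2).
#' @param extent numeric length-2, physical size in mm (for the arch,
#'   `extent[1]` is arc length).
#' @param radius radius specification: `list(type = "constant", r0 = 2)`,
#'   `list(type = "linear", r0 = , slope = )` (gradient along u, mm/mm) or
#'   `list(type = "bump", r0 = , amp = , center = c(u, v), width = )`.
#' @param tract_name,hemisphere surface metadata.
#' @return a [medial_surface()] with a `grid` attribute (`c(nu, nv)`) and
#'   per-vertex `tangent_u` attribute (unit tangent along the u
#'   direction, used to orient synthetic tensors).
#' @export
gen_surface <- function(kind = c("flat_sheet", "curved_sheet", "arch"),
                        nu = 20L, nv = 10L, extent = c(40, 20),
                        radius = list(type = "constant", r0 = 2),
                        tract_name = "synthetic", hemisphere = "midline") {
  kind <- match.arg(kind)
  if (nu < 2L || nv < 2L) stop("'nu' and 'nv' must be >= 2")
  if (any(extent <= 0)) stop("'extent' must be positive")
  u <- seq(0, extent[1], length.out = nu)
  v <- seq(0, extent[2], length.out = nv)
  uu <- rep(u, times = nv)
  vv <- rep(v, each = nu)
  verts <- switch(kind,
    flat_sheet = cbind(uu, vv, 0),
    curved_sheet = cbind(uu, vv, 0.1 * extent[1] * sin(pi * uu / extent[1])),
    arch = {
      theta_tot <- pi / 2
      R <- extent[1] / theta_tot
      th <- theta_tot * uu / extent[1]
      cbind(R * sin(th), vv, R * (1 - cos(th)))
    })
  colnames(verts) <- NULL

  id <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), times = nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  tris <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))

  r <- switch(radius$type,
    constant = rep(radius$r0, nu * nv),
    linear = radius$r0 + radius$slope * uu,
    bump = radius$r0 + radius$amp *
      exp(-((uu - radius$center[1])^2 + (vv - radius$center[2])^2) /
            (2 * radius$width^2)),
    stop("unknown radius type"))
  if (any(r <= 0)) stop("radius specification yields non-positive radius")

  surf <- medial_surface(verts, tris, r, tract_name = tract_name,
                         hemisphere = hemisphere)
  # unit tangent along u (central differences on the grid)
  gi <- rep(seq_len(nu), times = nv)
  tan_u <- verts[id(pmin(gi + 1L, nu), rep(seq_len(nv), each = nu)), ] -
    verts[id(pmax(gi - 1L, 1L), rep(seq_len(nv), each = nu)), ]
  tan_u <- tan_u / sqrt(rowSums(tan_u^2))
  attr(surf, "grid") <- c(nu = nu, nv = nv)
  attr(surf, "u") <- uu
  attr(surf, "v") <- vv
  attr(surf, "tangent_u") <- tan_u
  surf
}

#' Generate a cross-sectional study cohort
#'
#' Subjects with uniform ages on `[age_min, age_max]` (or the
#' study-matched truncated-normal preset reproducing the empirical age
#' moments 15.6 +/- 6.1 y for males and 16.0 +/- 6.4 y for females) and a
#' fixed sex split: `round(n * female_fraction)` females. Defaults
#' emulate the study cohort: 178 subjects aged 6-30, 83 male / 95 female.
#'
#' @param n number of subjects.
#' @param age_min,age_max age range in years.
#' @param female_fraction fraction of females in \[0, 1\].
#' @param seed integer seed (RNG state is restored afterwards).
#' @param age_dist "uniform" (default; best design coverage for recovery
#'   experiments) or "study" (truncated normal matched to the empirical
#'   moments).
#' @return data.frame with columns `id`, `age`, `sex` ("M"/"F").
#' @export
gen_cohort <- function(n = 178L, age_min = 6, age_max = 30,
                       female_fraction = 95 / 178, seed = NULL,
                       age_dist = c("uniform", "study")) {
  age_dist <- match.arg(age_dist)
  if (n < 0) stop("'n' must be non-negative")
  if (age_min >= age_max) stop("'age_min' must be below 'age_max'")
  if (female_fraction < 0 || female_fraction > 1)
    stop("'female_fraction' must be in [0, 1]")
  n_f <- as.integer(round(n * female_fraction))
  n_m <- as.integer(n) - n_f
  sex <- c(rep("M", n_m), rep("F", n_f))
  with_seed(seed, {
    age <- if (age_dist == "uniform") stats::runif(n, age_min, age_max)
    else {
      # underlying normal parameters chosen so the truncated moments
      # match the study's empirical per-sex moments
      pm <- .trunc_norm_match(15.6, 6.1, age_min, age_max)
      pf_ <- .trunc_norm_match(16.0, 6.4, age_min, age_max)
      mu <- ifelse(sex == "M", pm[1], pf_[1])
      sg <- ifelse(sex == "M", pm[2], pf_[2])
      lo <- stats::pnorm(age_min, mu, sg)
      hi <- stats::pnorm(age_max, mu, sg)
      stats::qnorm(stats::runif(n, lo, hi), mu, sg)
    }
    data.frame(id = sprintf("S%04d", seq_len(n)), age = age, sex = sex,
               stringsAsFactors = FALSE)
  })
}

#' Default regional growth designs
#'
#' Splits the surface into bands along the u coordinate and assigns each
#' band maturation parameters taken from the published tract-level
#' values: seven exponential regions carrying the per-tract female time
#' constants and yearly rates (with per-region male time-constant ratios),
#' one region with a purely linear trend, and one region with no age
#' effect. Total change over the age window is converted to the
#' exponential amplitude via
#' `A = delta / (exp(-age_max/t) - exp(-age_min/t))`.
#'
#' @param surface a [gen_surface()] mesh (any [medial_surface()] works;
#'   bands are cut along the first coordinate).
#' @param measure "fa" or "md".
#' @return list of region specifications for [gen_growth_field()].
#' @export
default_growth_regions <- function(surface, measure = c("fa", "md")) {
  measure <- match.arg(measure)
  if (measure == "fa") {
    t_f <- c(2.8, 4.3, 4.4, 4.1, 3.6, 5.8, 5.0)
    t_m <- c(5.5, 5.3, 5.3, 6.2, 6.8, 6.4, 7.6)
    rate <- c(0.010, 0.010, 0.007, 0.008, 0.009, 0.004, 0.006)
    Cmid <- 0.55; Cjit <- 0.03
    lin_slope <- 0.003; lin_int <- 0.45
    sgn <- +1
  } else {
    t_f <- c(2.7, 3.2, 4.4, 3.3, 4.3, 4.7, 4.2)
    t_m <- c(5.9, 7.1, 6.0, 7.6, 6.9, 6.7, 10.3)
    rate <- c(0.014, 0.012, 0.008, 0.009, 0.008, 0.008, 0.007) * 1e-3
    Cmid <- 0.70e-3; Cjit <- 0.03e-3
    lin_slope <- -0.004e-3; lin_int <- 0.82e-3
    sgn <- -1
  }
  u <- surface$vertices[, 1]
  br <- stats::quantile(u, probs = seq(0, 1, length.out = 10),
                        names = FALSE)
  band <- findInterval(u, br[-c(1, 10)]) + 1L  # 1..9
  regions <- vector("list", 9L)
  ln10 <- log(10)
  for (k in 1:7) {
    delta <- sgn * rate[k] * t_f[k] * ln10 / 0.9  # total change 6 -> plateau/0.9
    regions[[k]] <- list(vertices = which(band == k),
                         model = "exponential",
                         t = t_f[k] * c(0.9, 1.1),
                         C = Cmid + Cjit * c(-1, 1),
                         delta = delta * c(0.9, 1.1),
                         sex_t_mult = t_m[k] / t_f[k])
  }
  regions[[8]] <- list(vertices = which(band == 8L), model = "linear",
                       slope = lin_slope * c(0.8, 1.2),
                       intercept = lin_int * c(0.98, 1.02))
  regions[[9]] <- list(vertices = which(band == 9L), model = "none",
                       C = Cmid + Cjit * c(-1, 1))
  regions
}

#' Generate a ground-truth growth field
#'
#' Draws per-vertex maturation parameters region by region (uniformly
#' within the region's ranges), then spatially smooths each parameter map
#' within its region so the field satisfies the smoothness the analysis
#' assumes (correlation length at or above the measurement smoothing
#' scale). The exponential model per vertex and sex is
#' `C + A * exp(-age / t)` with a sex effect expressed as a
#' multiplicative factor on the time constant (and optionally an additive
#' offset on the asymptote) for males.
#'
#' @param surface a [medial_surface()].
#' @param regions list of region specs (see [default_growth_regions()]);
#'   each needs `vertices` plus, by model: exponential `t`, `C`, `delta`
#'   (total change over the age window; positive = increase) and optional
#'   `sex_t_mult`, `sex_C_offset`; linear `slope`, `intercept`; none `C`.
#'   Scalars or `c(lo, hi)` ranges. Regions must partition the vertices.
#' @param measure "fa" or "md" (sets units and the default noise SD:
#'   0.03 FA, 0.05e-3 mm^2/s MD).
#' @param noise_sd measurement noise SD added by [gen_vertex_measures()].
#' @param smooth_fwhm within-region smoothing of parameter maps, mm.
#' @param age_min,age_max the modeled age window, years.
#' @param seed integer seed.
#' @return object of class `growth_field`: per-vertex `model`, `C`, `A`,
#'   `t`, `slope`, `intercept`, `sex_t_mult`, `sex_C_offset`, plus
#'   `noise_sd`, `measure`, `age_min`, `age_max`.
#' @export
gen_growth_field <- function(surface, regions = NULL,
                             measure = c("fa", "md"), noise_sd = NULL,
                             smooth_fwhm = 8, age_min = 6, age_max = 30,
                             seed = NULL) {
  measure <- match.arg(measure)
  if (is.null(regions)) regions <- default_growth_regions(surface, measure)
  if (is.null(noise_sd)) noise_sd <- if (measure == "fa") 0.03 else 0.05e-3
  nv <- nrow(surface$vertices)
  cover <- sort(unlist(lapply(regions, `[[`, "vertices")))
  if (!identical(cover, seq_len(nv)))
    stop("regions must partition the vertices")
  if (any(vapply(regions, function(r) length(r$vertices) == 0L, TRUE)))
    stop("empty region")

  draw <- function(spec, m) {
    if (is.null(spec)) rep(NA_real_, m)
    else if (length(spec) == 1L) rep(spec, m)
    else stats::runif(m, min(spec), max(spec))
  }
  model <- character(nv)
  C <- A <- tt <- slope <- intercept <- rep(NA_real_, nv)
  mult <- rep(1, nv); coff <- rep(0, nv)
  with_seed(seed, {
    for (rg in regions) {
      vi <- rg$vertices; m <- length(vi)
      model[vi] <- rg$model
      if (rg$model == "exponential") {
        tt[vi] <- draw(rg$t, m)
        C[vi] <- draw(rg$C, m)
        delta <- draw(rg$delta, m)
        A[vi] <- delta / (exp(-age_max / tt[vi]) - exp(-age_min / tt[vi]))
        mult[vi] <- if (is.null(rg$sex_t_mult)) 1 else
          draw(rg$sex_t_mult, m)
        coff[vi] <- if (is.null(rg$sex_C_offset)) 0 else
          draw(rg$sex_C_offset, m)
      } else if (rg$model == "linear") {
        slope[vi] <- draw(rg$slope, m)
        intercept[vi] <- draw(rg$intercept, m)
      } else if (rg$model == "none") {
        C[vi] <- draw(rg$C, m)
      } else stop("unknown model in region spec")
    }
  })
  if (smooth_fwhm > 0) {
    for (rg in regions) {
      vi <- rg$vertices
      for (nm in c("C", "A", "tt", "slope", "intercept", "mult")) {
        val <- get(nm)
        if (all(is.na(val[vi]))) next
        masked <- rep(NA_real_, nv)
        masked[vi] <- val[vi]
        sm <- heat_smooth(surface, masked, smooth_fwhm)
        val[vi] <- sm[vi]
        assign(nm, val)
      }
    }
  }
  if (any(model == "exponential" & (!is.finite(tt) | tt <= 0)))
    stop("exponential regions require positive time constants")
  structure(list(model = model, C = C, A = A, t = tt, slope = slope,
                 intercept = intercept, sex_t_mult = mult,
                 sex_C_offset = coff, noise_sd = noise_sd,
                 measure = measure, age_min = age_min, age_max = age_max),
            class = "growth_field")
}

#' @export
print.growth_field <- function(x, ...) {
  cat(sprintf("Growth field (%s): %d vertices [%s], noise SD %g\n",
              toupper(x$measure), length(x$model),
              paste(sprintf("%s %d", names(table(x$model)),
                            as.integer(table(x$model))), collapse = ", "),
              x$noise_sd))
  invisible(x)
}

#' Evaluate the noiseless growth curves of a field
#'
#' @param field a [gen_growth_field()] result.
#' @param ages numeric vector of ages, years.
#' @param sex "M" or "F" (the sex effect scales male time constants).
#' @param vertices vertex subset (default all).
#' @return length(ages) x length(vertices) matrix of noiseless values.
#' @export
growth_curve <- function(field, ages, sex = "F",
                         vertices = seq_along(field$model)) {
  te <- field$t[vertices]
  Ce <- field$C[vertices]
  if (identical(sex, "M")) {
    te <- te * field$sex_t_mult[vertices]
    Ce <- Ce + field$sex_C_offset[vertices]
  }
  out <- matrix(NA_real_, length(ages), length(vertices))
  mdl <- field$model[vertices]
  ex <- mdl == "exponential"
  if (any(ex))
    out[, ex] <- outer(ages, seq_len(sum(ex)), function(a, j)
      Ce[ex][j] + field$A[vertices][ex][j] * exp(-a / te[ex][j]))
  li <- mdl == "linear"
  if (any(li))
    out[, li] <- outer(ages, seq_len(sum(li)), function(a, j)
      field$intercept[vertices][li][j] + field$slope[vertices][li][j] * a)
  no <- mdl == "none"
  if (any(no))
    out[, no] <- matrix(Ce[no], length(ages), sum(no), byrow = TRUE)
  out
}

#' Ground-truth plateau ages of a growth field
#'
#' The age at which 90 percent of the remaining change from `age_min`
#' toward the asymptote is complete: exactly `age_min + t * ln(10)`.
#'
#' @inheritParams growth_curve
#' @return numeric per-vertex plateau age (NA at non-exponential
#'   vertices).
#' @export
true_plateau_age <- function(field, sex = "F") {
  te <- field$t
  if (identical(sex, "M")) te <- te * field$sex_t_mult
  ifelse(field$model == "exponential", field$age_min + te * log(10),
         NA_real_)
}

#' Generate per-vertex measurements for a cohort
#'
#' Evaluates the growth curves at each subject's age and sex and adds
#' independent Gaussian measurement noise (the field's `noise_sd`); FA is
#' clipped to \[0, 1\]. An optional missingness rate knocks out random
#' (subject, vertex) entries jointly in FA and MD.
#'
#' @param surface a [medial_surface()] the fields live on.
#' @param subjects a [gen_cohort()] table.
#' @param field_fa,field_md growth fields for FA and MD; either may be
#'   NULL, in which case that measure is filled with a flat default level
#'   (0.55 FA, 0.7e-3 MD) plus its default noise.
#' @param missing_rate probability an entry is missing.
#' @param seed integer seed.
#' @return a [vertex_measures()] object.
#' @export
gen_vertex_measures <- function(surface, subjects, field_fa = NULL,
                                field_md = NULL, missing_rate = 0,
                                seed = NULL) {
  if (is.null(field_fa) && is.null(field_md))
    stop("provide at least one growth field")
  nv <- nrow(surface$vertices)
  ns <- nrow(subjects)
  gen_one <- function(field, default_level, default_sd, clip) {
    out <- matrix(NA_real_, ns, nv)
    if (is.null(field)) {
      out[] <- default_level +
        stats::rnorm(ns * nv, 0, default_sd)
    } else {
      for (sx in unique(subjects$sex)) {
        rows <- which(subjects$sex == sx)
        out[rows, ] <- growth_curve(field, subjects$age[rows], sx)
      }
      out <- out + stats::rnorm(ns * nv, 0, field$noise_sd)
    }
    if (clip) out <- pmin(pmax(out, 0), 1)
    out
  }
  with_seed(seed, {
    fa <- gen_one(field_fa, 0.55, 0.03, clip = TRUE)
    md <- gen_one(field_md, 0.7e-3, 0.05e-3, clip = FALSE)
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(ns * nv) < missing_rate, ns, nv)
      fa[drop] <- NA_real_
      md[drop] <- NA_real_
    }
    rownames(fa) <- rownames(md) <- subjects$id
    vertex_measures(fa, md, subjects)
  })
}

# closed-form prolate tensor with prescribed FA and MD:
# lambda1 = MD + 2*delta, lambda2 = lambda3 = MD - delta,
# delta = FA * MD / sqrt(3 - 2 FA^2)  (unique, invertible for FA < 1)
.prolate_eigs <- function(fa, md) {
  delta <- fa * md / sqrt(3 - 2 * fa^2)
  cbind(md + 2 * delta, md - delta)
}

#' Embed a growth field in a synthetic tensor volume
#'
#' Builds a diffusion tensor volume in which every voxel inside the
#' tract's medial envelope (the union of balls of the local radius around
#' skeleton points) carries a prolate tensor whose FA and MD equal the
#' field's noiseless curve values at the subject's age, with the
#' principal axis along the local surface tangent. The background is
#' isotropic with MD `background_md` and FA 0, below any projection
#' threshold. Projecting this volume through the spokes recovers the
#' prescribed per-vertex values up to interpolation error, giving an
#' end-to-end fixture for the projection stage.
#'
#' @param surface a [gen_surface()] mesh (its `tangent_u` attribute
#'   orients the tensors).
#' @param subject one row of a [gen_cohort()] table.
#' @param field_fa,field_md growth fields (MD optional; defaults to a
#'   flat 0.7e-3 mm^2/s).
#' @param voxel_size isotropic voxel edge, mm.
#' @param background_md isotropic background diffusivity, mm^2/s.
#' @param margin extra padding around the envelope, voxels.
#' @return a [dt_volume()].
#' @export
gen_tensor_volume <- function(surface, subject, field_fa, field_md = NULL,
                              voxel_size = 1, background_md = 0.7e-3,
                              margin = 2L) {
  v <- surface$vertices
  r <- surface$radius
  lo <- apply(v, 2, min) - max(r) - margin * voxel_size
  hi <- apply(v, 2, max) + max(r) + margin * voxel_size
  dims <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 2L)
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- lo

  fa_t <- as.vector(growth_curve(field_fa, subject$age, subject$sex))
  md_t <- if (is.null(field_md)) rep(0.7e-3, nrow(v)) else
    as.vector(growth_curve(field_md, subject$age, subject$sex))
  tan_u <- attr(surface, "tangent_u")
  if (is.null(tan_u)) {
    # fallback: any unit tangent orthogonal to the normal
    ref <- matrix(rep(c(1, 0, 0), each = nrow(v)), ncol = 3)
    tan_u <- ref - surface$normals * rowSums(ref * surface$normals)
    tan_u <- tan_u / sqrt(rowSums(tan_u^2))
  }

  nvox <- prod(dims)
  D6 <- matrix(0, nvox, 6)
  D6[, c(1, 3, 6)] <- background_md
  # voxel centers in world mm (0-based indices)
  ix <- (seq_len(dims[1]) - 1) * voxel_size + lo[1]
  iy <- (seq_len(dims[2]) - 1) * voxel_size + lo[2]
  iz <- (seq_len(dims[3]) - 1) * voxel_size + lo[3]
  centers <- cbind(rep(ix, times = dims[2] * dims[3]),
                   rep(rep(iy, each = dims[1]), times = dims[3]),
                   rep(iz, each = dims[1] * dims[2]))
  chunk <- 20000L
  for (start in seq(1L, nvox, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nvox)
    d2 <- outer(rowSums(centers[idx, , drop = FALSE]^2), rowSums(v^2), "+") -
      2 * centers[idx, , drop = FALSE] %*% t(v)
    near <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(pmax(d2[cbind(seq_along(idx), near)], 0))
    inside <- dmin <= r[near] & !is.na(fa_t[near])
    if (!any(inside)) next
    k <- near[inside]
    le <- .prolate_eigs(fa_t[k], md_t[k])
    dl <- le[, 1] - le[, 2]
    e <- tan_u[k, , drop = FALSE]
    rows <- idx[inside]
    D6[rows, 1] <- le[, 2] + dl * e[, 1]^2
    D6[rows, 2] <- dl * e[, 1] * e[, 2]
    D6[rows, 3] <- le[, 2] + dl * e[, 2]^2
    D6[rows, 4] <- dl * e[, 1] * e[, 3]
    D6[rows, 5] <- dl * e[, 2] * e[, 3]
    D6[rows, 6] <- le[, 2] + dl * e[, 3]^2
  }
  dt_volume(array(D6, dim = c(dims, 6L)), affine)
}
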