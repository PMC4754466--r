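#' Tract-level summary of vertexwise maturation results
#'
#' Aggregates per-vertex model selections into the tract-table quantities:
#' percentage of valid vertices with each significant model (P_exp,
#' P_lin), mean fit correlations over each model's mask, mean exponential
#' time constant and its mean standard error, mean yearly rates, and the
#' plateau age derived from the mean time constant. Because the plateau
#' age is linear in t, `mean_T = age_min + ln(10) * mean_t` holds exactly;
#' the tract-level `mean_se_T` is `ln(10) * mean(se_t)` (the mean of
#' per-vertex standard errors -- self-consistent with per-vertex
#' propagation). The between-sex flag applies the one-standard-error
#' overlap rule to the tract-level estimates of the two sexes.
#'
#' @param results a [infer_vertices()] table (one or both sexes).
#' @param tract tract label carried into the output.
#' @param age_min start of the modeled window, years.
#' @return data.frame of class `tract_summary`, one row per sex, with a
#'   `sex_diff` attribute from [sex_overlap_test()] when both sexes are
#'   present. Zero valid vertices yield an `empty = TRUE` row.
#' @export
tract_summary <- function(results, tract = "tract", age_min = 6) {
  measure <- attr(results, "measure")
  rows <- lapply(unique(results$sex), function(sx) {
    rr <- results[results$sex == sx, ]
    valid <- rr[!is.na(rr$n) & rr$n > 0, ]
    nvalid <- nrow(valid)
    if (nvalid == 0L)
      return(data.frame(tract = tract, sex = sx, measure = measure,
                        n_vertices = 0L, p_exp = NA_real_,
                        p_lin = NA_real_, mean_r_exp = NA_real_,
                        mean_r_lin = NA_real_, mean_t = NA_real_,
                        mean_se_t = NA_real_, mean_rate_exp = NA_real_,
                        mean_rate_lin = NA_real_, mean_T = NA_real_,
                        mean_se_T = NA_real_, empty = TRUE,
                        stringsAsFactors = FALSE))
    me <- valid$chosen_model == "exponential"
    ml <- valid$chosen_model == "linear"
    mean_t <- mean(valid$exp_t[me])
    mean_se_t <- mean(valid$exp_se_t[me])
    data.frame(tract = tract, sex = sx, measure = measure,
               n_vertices = nvalid,
               p_exp = 100 * mean(me), p_lin = 100 * mean(ml),
               mean_r_exp = mean(abs(valid$exp_r[me])),
               mean_r_lin = mean(abs(valid$lin_r[ml])),
               mean_t = mean_t, mean_se_t = mean_se_t,
               mean_rate_exp = mean(valid$rate[me]),
               mean_rate_lin = mean(valid$rate[ml]),
               mean_T = age_min + log(10) * mean_t,
               mean_se_T = log(10) * mean_se_t,
               empty = FALSE, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    out <- data.frame(tract = character(0), sex = character(0),
                      measure = character(0), n_vertices = integer(0),
                      empty = logical(0))
    class(out) <- c("tract_summary", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  if (all(c("M", "F") %in% out$sex)) {
    f <- out[out$sex == "F", ]
    m <- out[out$sex == "M", ]
    attr(out, "sex_diff") <- sex_overlap_test(f$mean_T, f$mean_se_T,
                                              m$mean_T, m$mean_se_T)
  }
  class(out) <- c("tract_summary", "data.frame")
  out
}

#' @export
print.tract_summary <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Tract summary: no vertices\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)
  df$p_exp <- round_half_up(df$p_exp, 0)
  df$p_lin <- round_half_up(df$p_lin, 0)
  for (cl in c("mean_t", "mean_se_t", "mean_T", "mean_se_T"))
    df[[cl]] <- round_half_up(df[[cl]], 1)
  for (cl in c("mean_rate_exp", "mean_rate_lin", "mean_r_exp",
               "mean_r_lin"))
    df[[cl]] <- signif(df[[cl]], 3)
  print.data.frame(df[, setdiff(names(df), "empty")], row.names = FALSE)
  sd_ <- attr(x, "sex_diff")
  if (!is.null(sd_) && isTRUE(sd_$significant))
    cat(sprintf("  sex difference: %s earlier (1-SE intervals disjoint)\n",
                sd_$earlier))
  invisible(x)
}

#' Round half away from zero
#'
#' Deterministic table rounding (R's `round` is round-half-even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Combine left and right hemisphere results
#'
#' Fitting stays per side; the significant-vertex sets are pooled (the
#' union over the two surfaces) before tract-level summary statistics,
#' as in left+right tract tables. The pooled summary's masked means are
#' therefore vertex-count-weighted means of the side means.
#'
#' @param results_left,results_right [infer_vertices()] tables from the
#'   two hemisphere surfaces, produced with identical settings.
#' @return a combined `vertex_results` table with a `side` column.
#' @export
combine_hemispheres <- function(results_left, results_right) {
  if (!identical(attr(results_left, "measure"),
                 attr(results_right, "measure")))
    stop("hemisphere results disagree on measure")
  if (!setequal(unique(results_left$sex), unique(results_right$sex)))
    stop("hemisphere results disagree on sex groups")
  results_left$side <- "L"
  results_right$side <- "R"
  out <- rbind(results_left, results_right)
  class(out) <- c("vertex_results", "data.frame")
  attr(out, "measure") <- attr(results_left, "measure")
  out
}

#' Mean trajectory over a vertex mask
#'
#' Per subject, the mean of the measure over the masked vertices (the
#' tract-average series behind trajectory figures), plus a per-sex group
#' fit of the requested model to the subject means with plateau markers
#' for exponential fits.
#'
#' @param measures a [vertex_measures()].
#' @param mask integer vertex indices (e.g. the significant-exponential
#'   set).
#' @param measure "fa" or "md".
#' @param model "exponential" or "linear" group fit.
#' @param age_min,age_max modeled window for the plateau marker.
#' @return list with `series` (data.frame id, age, sex, mean_value) and
#'   `fits` (per-sex growth fits, with `plateau` for exponential). An
#'   empty mask returns an explicitly empty result.
#' @export
mean_trajectory <- function(measures, mask, measure = c("fa", "md"),
                            model = c("exponential", "linear"),
                            age_min = 6, age_max = 30) {
  model <- match.arg(model)
  measure <- match.arg(measure)
  if (length(mask) == 0L)
    return(list(series = data.frame(), fits = list(), empty = TRUE))
  vals <- measures[[measure]]
  subj <- measures$subjects
  mu <- rowMeans(vals[, mask, drop = FALSE], na.rm = TRUE)
  series <- data.frame(id = subj$id, age = subj$age, sex = subj$sex,
                       mean_value = mu, stringsAsFactors = FALSE)
  fits <- list()
  for (sx in unique(subj$sex)) {
    rows <- subj$sex == sx
    ft <- tryCatch(
      if (model == "exponential")
        fit_exponential(subj$age[rows], mu[rows])
      else fit_linear(subj$age[rows], mu[rows]),
      tractmat_unfittable = function(e) NULL)
    if (!is.null(ft) && model == "exponential" && isTRUE(ft$converged))
      ft$plateau <- plateau_age(ft, age_min = age_min, age_max = age_max)
    fits[[sx]] <- ft
  }
  list(series = series, fits = fits, empty = FALSE)
}

#' Published tract-level reference fits
#'
#' The printed per-tract, per-sex trajectory parameters (percentage of
#' vertices with each significant model, fit correlations, exponential
#' time constants, yearly rates, plateau ages with standard errors, and
#' the between-sex significance marks) for FA and MD, shipped as plain
#' CSV. These published values serve as arithmetic cross-check inputs for
#' the plateau-age, overlap-rule and table-summary utilities.
#'
#' @param measure "fa", "md" or "both".
#' @return data.frame with columns `measure`, `tract`, `sex`, `p_exp`,
#'   `p_lin`, `r_exp`, `r_lin`, `t`, `se_t`, `rate_exp`, `rate_lin`,
#'   `T`, `se_T`, `sex_sig`.
#' @export
reference_tract_fits <- function(measure = c("both", "fa", "md")) {
  measure <- match.arg(measure)
  path <- system.file("extdata", "reference_fits.csv",
                      package = "tractmat", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (measure != "both") df <- df[df$measure == measure, ]
  df
}

#' Cross-check summaries of the reference tables
#'
#' Recomputes, from the printed per-tract values, the cohort-level
#' aggregates quoted alongside the tables: mean and SD of the
#' significant-vertex percentages per model, the combined
#' (exponential-or-linear) percentage, the female-minus-male exponential
#' percentage differences, per-sex mean plateau ages across tracts, and
#' the set of tracts whose female and male plateau-age intervals are
#' disjoint under the one-standard-error overlap rule.
#'
#' @param ref a [reference_tract_fits()] table for one measure.
#' @return list with `mean_p_exp`, `sd_p_exp`, `mean_p_lin`, `sd_p_lin`,
#'   `mean_p_combined`, `fm_diff_p_exp` (mean female-minus-male),
#'   `mean_T_by_sex`, and `sig_tracts` from the overlap rule.
#' @export
summarize_reference_fits <- function(ref) {
  stopifnot(length(unique(ref$measure)) == 1L)
  f <- ref[ref$sex == "F", ]
  m <- ref[ref$sex == "M", ]
  m <- m[match(f$tract, m$tract), ]
  ov <- sex_overlap_test(f$T, f$se_T, m$T, m$se_T)
  list(mean_p_exp = mean(ref$p_exp), sd_p_exp = stats::sd(ref$p_exp),
       mean_p_lin = mean(ref$p_lin), sd_p_lin = stats::sd(ref$p_lin),
       mean_p_combined = mean(ref$p_exp + ref$p_lin),
       fm_diff_p_exp = mean(f$p_exp - m$p_exp),
       mean_T_by_sex = c(F = mean(f$T), M = mean(m$T)),
       sig_tracts = sort(f$tract[which(ov$significant)]))
}
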