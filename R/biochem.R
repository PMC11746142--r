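#' ATPase activity from phosphate release
#'
#' The average ATPase activity is the phosphate released per protein and
#' time, `delta_Pi / (protein * delta_t)`, in inverse hours. All arguments
#' are vectorized.
#'
#' @param delta_Pi_uM Phosphate released, in micromolar (>= 0).
#' @param protein_uM Protein concentration, micromolar (> 0).
#' @param delta_t_h Incubation time in hours (> 0).
#' @return Activity in 1/h.
#' @examples
#' atpase_activity(15, 5, 1)  # 3 per hour
#' @export
atpase_activity <- function(delta_Pi_uM, protein_uM, delta_t_h) {
  if (any(!is.finite(delta_Pi_uM)) || any(delta_Pi_uM < 0)) {
    abort("`delta_Pi_uM` must be non-negative.")
  }
  if (any(!is.finite(protein_uM)) || any(protein_uM <= 0)) {
    abort("`protein_uM` must be positive.")
  }
  if (any(!is.finite(delta_t_h)) || any(delta_t_h <= 0)) {
    abort("`delta_t_h` must be positive.")
  }
  delta_Pi_uM / (protein_uM * delta_t_h)
}

#' Per-measurement activity table
#'
#' Adds an `activity_per_h` column to a measurement table with columns
#' `delta_Pi_uM`, `protein_uM` and `time_h`.
#'
#' @param data A data frame of measurements.
#' @return `data` as a tibble with `activity_per_h` appended.
#' @export
activity_table <- function(data) {
  needed <- c("delta_Pi_uM", "protein_uM", "time_h")
  if (!all(needed %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(needed, collapse = ", ")))
  }
  dplyr::mutate(as_tibble(data),
                activity_per_h = atpase_activity(.data$delta_Pi_uM,
                                                 .data$protein_uM,
                                                 .data$time_h))
}

#' Fit a phosphate (or ADP) standard curve
#'
#' Ordinary least-squares regression of absorbance on concentration:
#' `A = slope * c + intercept`. Unknowns are read off the inverted curve
#' after background correction.
#'
#' @param concentration_uM Standard concentrations (>= 3 points, >= 2
#'   distinct values).
#' @param absorbance Measured absorbances.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared` and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(concentration_uM, absorbance) {
  if (length(concentration_uM) != length(absorbance) ||
      length(concentration_uM) < 3) {
    abort("need at least 3 paired standard points.")
  }
  if (length(unique(concentration_uM)) < 2) {
    abort("standard concentrations have no variance; cannot fit a line.")
  }
  fit <- lm(absorbance ~ concentration_uM,
            data = data.frame(concentration_uM = concentration_uM,
                              absorbance = absorbance))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> A = %.4g * c + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param curve A fitted `standard_curve`.
#' @param background Background absorbance subtracted before inversion
#'   (ATP/protein blank).
#' @return `invert_standard_curve()`: concentration in micromolar.
#' @export
invert_standard_curve <- function(curve, absorbance, background = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  (absorbance - background - curve$intercept) / curve$slope
}

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = length(x$fit$residuals))
}

#' Activity relative to a reference group
#'
#' Percent of the reference mean activity, and the corresponding percent
#' reduction (mutant assays are reported as "reduced by X percent").
#'
#' @param group Activities of the group of interest.
#' @param reference Activities of the reference (e.g. wild type); mean must
#'   be positive.
#' @return A one-row tibble with `percent_of_reference` and
#'   `percent_reduction`.
#' @examples
#' relative_activity(c(0.3, 0.32), c(3, 3.1))
#' @export
relative_activity <- function(group, reference) {
  if (length(group) == 0) abort("`group` must be non-empty.")
  if (length(reference) == 0 || mean(reference) <= 0) {
    abort("`reference` must be non-empty with positive mean.")
  }
  pct <- 100 * mean(group) / mean(reference)
  tibble(percent_of_reference = pct, percent_reduction = 100 - pct)
}

#' Two-sided two-sample t-test
#'
#' Welch's unequal-variance t-test by default (switchable to the pooled
#' variant). When both samples are constant with equal means, the test is
#' degenerate and `t = 0`, `p = 1` is returned.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param var_equal Use the pooled-variance test (default `FALSE`, Welch).
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least 2 observations.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = NA_real_, p_value = 1,
                    mean_a = mean(a), mean_b = mean(b)))
    }
    abort("both samples are constant with different means; t is undefined.")
  }
  ht <- t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Group summary in boxplot convention
#'
#' Mean with standard error (sample s.d. over sqrt n), 10th and 90th
#' percentiles (linear interpolation) as whiskers, and the values outside
#' the whiskers as outliers.
#'
#' @param values Numeric vector (n >= 1).
#' @return A one-row tibble: `n`, `mean`, `sem`, `p10`, `p90`,
#'   `n_outliers` and a list-column `outliers`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0 || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector.")
  }
  q <- quantile(values, c(0.1, 0.9), type = 7, names = FALSE)
  out <- values[values < q[1] | values > q[2]]
  tibble(n = length(values), mean = mean(values),
         sem = if (length(values) > 1) sd(values) / sqrt(length(values)) else 0,
         p10 = q[1], p90 = q[2],
         n_outliers = length(out), outliers = list(out))
}
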