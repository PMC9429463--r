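#' Per-measurement relative error
#'
#' `RE_i = (x_i - x_ir) / x_ir * 100`, with `x_i` the measured and `x_ir` the
#' reference FVC (both in percent). Reference values of exactly zero make the
#' statistic undefined; the function raises an error naming the offending
#' index rather than dropping pairs silently.
#'
#' @param measured,reference Equal-length numeric vectors of FVC values
#'   (percent).
#' @return Numeric vector of relative errors (percent), order-preserving.
#' @examples
#' relative_error(12, 10)  # 20
#' @export
relative_error <- function(measured, reference) {
  check_pairs(measured, reference)
  (measured - reference) / reference * 100
}

check_pairs <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("measured and reference must have equal length", call. = FALSE)
  }
  if (length(measured) < 1L) stop("at least one pair is required", call. = FALSE)
  if (anyNA(measured) || anyNA(reference)) {
    stop("measured and reference must not contain NA", call. = FALSE)
  }
  zero <- which(reference == 0)
  if (length(zero)) {
    stop(sprintf(
      "reference FVC is zero at index %s; relative metrics are undefined",
      paste(zero, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Accuracy summary of measured vs reference FVC
#'
#' Computes the five accuracy statistics over paired measured/reference FVC
#' values, with `n` in every denominator (population means, no `n - 1`
#' correction):
#' \itemize{
#'   \item MAPE: mean of `|x_i - x_ir| / x_ir * 100` (percent)
#'   \item BIAS: mean of `x_i - x_ir` (percent points)
#'   \item relBIAS: mean of `x_i / x_ir - 1`, times 100 (percent)
#'   \item RMSE: root of the mean squared error (percent points)
#'   \item relRMSE: root of the mean squared relative error, times 100
#'     (percent)
#' }
#'
#' @inheritParams relative_error
#' @param algorithm_id,scenario_id Optional identifiers carried into report
#'   tables.
#' @return A list of class `"accuracy_summary"` with elements `mape`, `bias`,
#'   `rel_bias`, `rmse`, `rel_rmse`, `n`, `algorithm_id`, `scenario_id`.
#' @examples
#' accuracy_summary(c(11, 9), c(10, 10))
#' @export
accuracy_summary <- function(measured, reference,
                             algorithm_id = NA_character_,
                             scenario_id = NA_character_) {
  check_pairs(measured, reference)
  d <- measured - reference
  r <- measured / reference - 1
  structure(
    list(
      mape = mean(abs(r)) * 100,
      bias = mean(d),
      rel_bias = mean(r) * 100,
      rmse = sqrt(mean(d^2)),
      rel_rmse = sqrt(mean(r^2)) * 100,
      n = length(measured),
      algorithm_id = algorithm_id,
      scenario_id = scenario_id
    ),
    class = "accuracy_summary"
  )
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf(
    "Accuracy over n = %d pairs: MAPE %.2f%%, BIAS %.2f, relBIAS %.2f%%, RMSE %.2f, relRMSE %.2f%%\n",
    x$n, x$mape, x$bias, x$rel_bias, x$rmse, x$rel_rmse
  ))
  invisible(x)
}

#' Measured-on-reference linear regression
#'
#' Ordinary least squares of measured FVC on reference FVC, reporting slope,
#' intercept and the coefficient of determination. A perfect algorithm gives
#' slope 1, intercept 0, R-squared 1.
#'
#' @inheritParams relative_error
#' @return A list of class `"fvc_regression"` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_regression <- function(measured, reference) {
  check_pairs(measured, reference)
  n <- length(measured)
  if (n < 3L) stop("regression needs at least 3 pairs", call. = FALSE)
  if (length(unique(reference)) < 2L) {
    stop("degenerate design: reference values are all equal", call. = FALSE)
  }
  fit <- stats::lm(measured ~ reference)
  # R^2 from the residuals directly; summary.lm() warns on the exact fits
  # that noise-free synthetic scenes legitimately produce
  sst <- sum((measured - mean(measured))^2)
  # constant measured values explain nothing: R^2 = 0 by convention
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n = n
    ),
    class = "fvc_regression"
  )
}

#' Compare measured and reference FVC by analysis of variance
#'
#' One-way ANOVA between the measured set and the reference set (two groups),
#' the plainest test of whether an algorithm's coverage values differ
#' systematically from the truth. With two groups, F equals the square of the
#' pooled two-sample t statistic.
#'
#' Degenerate inputs are resolved before the F distribution is touched: equal
#' group means give `F = 0`, `p = 1`; distinct means with zero within-group
#' variance are exact separation, reported as `F = Inf`, `p = 0`.
#'
#' @inheritParams relative_error
#' @return A list of class `"fvc_comparison"` with `f_statistic`, `p_value`,
#'   `mean_difference` (measured minus reference, percent points), `n`.
#' @export
compare_groups <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("measured and reference must have equal length", call. = FALSE)
  }
  n <- length(measured)
  if (n < 2L) stop("analysis of variance needs at least 2 pairs", call. = FALSE)
  if (anyNA(measured) || anyNA(reference)) {
    stop("measured and reference must not contain NA", call. = FALSE)
  }
  md <- mean(measured) - mean(reference)
  ss_within <- sum((measured - mean(measured))^2) + sum((reference - mean(reference))^2)
  if (md == 0) {
    res <- list(f_statistic = 0, p_value = 1, mean_difference = 0, n = n)
  } else if (ss_within == 0) {
    res <- list(f_statistic = Inf, p_value = 0, mean_difference = md, n = n)
  } else {
    values <- c(measured, reference)
    group <- factor(rep(c("measured", "reference"), each = n))
    ow <- stats::oneway.test(values ~ group, var.equal = TRUE)
    res <- list(
      f_statistic = unname(ow$statistic),
      p_value = unname(ow$p.value),
      mean_difference = md,
      n = n
    )
  }
  structure(res, class = "fvc_comparison")
}

# Share of measurements in the relative-error bands used by the report
# tables: |RE| below 10/20/30 and above 50/100 percent.
re_distribution <- function(re) {
  a <- abs(re)
  c(
    re_lt10 = mean(a < 10),
    re_lt20 = mean(a < 20),
    re_lt30 = mean(a < 30),
    re_gt50 = mean(a > 50),
    re_gt100 = mean(a > 100)
  )
}
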