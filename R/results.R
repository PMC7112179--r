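#' Hypothesis-test result container
#'
#' Lightweight container used by every test in the package. Fields mirror
#' what the pipeline stages need downstream: the test statistic, the raw
#' p-value, an optional BH-adjusted p-value, an optional point estimate,
#' the method label and the alternative hypothesis.
#'
#' @param statistic numeric test statistic (may be `NA`).
#' @param p_value numeric p-value in `[0, 1]`, or `NA` when the test is
#'   degenerate.
#' @param estimate optional point estimate (odds ratio, tau, rate, ...).
#' @param method character label of the test performed.
#' @param alternative one of `"two.sided"`, `"less"`, `"greater"`, or `NA`.
#' @param p_adjusted optional multiplicity-adjusted p-value.
#' @param note optional character flag (e.g. `"degenerate margin"`).
#'
#' @return An object of class `"test_result"`.
#' @export
test_result <- function(statistic = NA_real_, p_value = NA_real_,
                        estimate = NA_real_, method = "test",
                        alternative = NA_character_,
                        p_adjusted = NA_real_, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(statistic = unname(statistic), p_value = unname(min(p_value, 1)),
         estimate = unname(estimate), method = method,
         alternative = alternative, p_adjusted = unname(p_adjusted),
         note = note),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("\t", x$method, "\n")
  if (!is.na(x$alternative)) cat("alternative:", x$alternative, "\n")
  if (!is.na(x$statistic)) cat("statistic  :", format(x$statistic), "\n")
  if (!is.na(x$estimate)) cat("estimate   :", format(x$estimate), "\n")
  cat("p-value    :", format(x$p_value), "\n")
  if (!is.na(x$p_adjusted)) cat("adjusted p :", format(x$p_adjusted), "\n")
  if (!is.null(x$note)) cat("note       :", x$note, "\n")
  invisible(x)
}

#' Ordinary least-squares regression summary
#'
#' Thin wrapper over [stats::lm()] returning only the quantities used by
#' the expression-fitness analyses: slope, intercept, the t-test p-value
#' for the slope and the adjusted R-squared
#' \eqn{1 - (1 - R^2)(n - 1)/(n - 2)}.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, finite.
#'
#' @return An object of class `"regression_result"` with fields `slope`,
#'   `intercept`, `slope_p`, `r2_adjusted`, `n`.
#' @examples
#' linear_regression(1:5, 2 * (1:5))
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3) stop("linear_regression requires n >= 3")
  if (stats::sd(x) == 0) stop("x has zero variance; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         slope_p = unname(sm$coefficients[2L, 4L]),
         r2_adjusted = sm$adj.r.squared,
         n = n),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("OLS fit (n =", x$n, ")\n")
  cat("  slope    :", format(x$slope), " (p =", format(x$slope_p), ")\n")
  cat("  intercept:", format(x$intercept), "\n")
  cat("  adj. R^2 :", format(x$r2_adjusted), "\n")
  invisible(x)
}
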