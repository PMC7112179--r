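# Core statistical kernel shared by every pipeline stage. These are thin,
# validated wrappers over the base R tests where a canonical implementation
# exists; the quasi-binomial transmission machinery is implemented here
# directly because the test (deviance drop against a *fixed* null rate,
# scaled by a Pearson dispersion estimated inside a pooling scope) is not a
# stock glm() summary.

#' Two-sided (or one-sided) Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test on a 2x2 contingency table. The two-sided
#' p-value follows the minimum-likelihood convention: the sum of
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. The estimate is the conditional maximum-likelihood
#' odds ratio.
#'
#' A table with a zero row or column margin carries no information against
#' independence; it returns `p = 1` with a warning rather than an error so
#' that batch comparisons over sparse classes do not abort.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome), or a length-4 vector `c(a, b, c, d)` filled by row.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#'
#' @return A [test_result] with the odds-ratio estimate.
#' @examples
#' # seed development at 4 days after pollination, mutant vs wild-type
#' fisher_exact_2x2(matrix(c(6, 6, 28, 0), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, byrow = TRUE)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (sum(tab) == 0) stop("at least one cell must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: a row or column sums to zero; p = 1")
    return(test_result(p_value = 1, estimate = NA_real_,
                       method = "Fisher's exact test (2x2)",
                       alternative = alternative,
                       note = "degenerate margin"))
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  test_result(p_value = ft$p.value, estimate = unname(ft$estimate),
              method = "Fisher's exact test (2x2)",
              alternative = alternative)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values to control the false discovery rate. `NA` entries are
#' passed through unchanged and are excluded from the number of tests `m`,
#' matching the convention of differential-expression pipelines where
#' filtered features carry `NA` p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; `NA` allowed.
#'
#' @return Numeric vector of the same length and order, adjusted values
#'   capped at 1, `NA` preserved in place.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Tie-corrected Kendall tau with a p-value from the normal approximation
#' to the tau-b null variance. Per-bin TE counts tie heavily, so the
#' tie-corrected variant is used throughout the coexpression analyses.
#' If either vector is entirely tied the correlation is undefined and a
#' flagged `NA` result is returned.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#'
#' @return A [test_result] with `estimate` (and `statistic`) = tau-b.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(test_result(method = "Kendall rank correlation (tau-b)",
                       alternative = "two.sided",
                       note = "all values tied; tau undefined"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  tau <- unname(ct$estimate)
  test_result(statistic = tau, p_value = ct$p.value, estimate = tau,
              method = "Kendall rank correlation (tau-b)",
              alternative = "two.sided")
}

# Binomial deviance of per-ear counts at a common success rate p.
# 0 * log(0) terms are dropped, as in the saturated-model convention.
binomial_deviance <- function(successes, totals, p) {
  term <- function(obs, expd) {
    out <- numeric(length(obs))
    pos <- obs > 0
    out[pos] <- obs[pos] * log(obs[pos] / expd[pos])
    out
  }
  2 * sum(term(successes, totals * p) +
          term(totals - successes, totals * (1 - p)))
}

#' Quasi-likelihood test of a common transmission rate against a null rate
#'
#' Fits the intercept-only quasi-binomial model (logit link) to per-ear
#' marked/total seed counts and tests the fitted rate against `null_rate`
#' with a quasi-likelihood F test. For the intercept-only model the
#' maximum-likelihood fitted rate is the pooled proportion
#' `sum(successes) / sum(totals)`; the iteratively reweighted least squares
#' fit converges there, so the closed form is used directly.
#'
#' Overdispersion is quantified by the Pearson dispersion
#' \deqn{\hat\phi = \sum_i \frac{(y_i - n_i\hat\mu)^2}{n_i\hat\mu(1-\hat\mu)} / (k - 1)}
#' over the `k` ears, unless `phi_override` supplies a dispersion pooled
#' over a wider scope (e.g. all ears of an expression class), in which case
#' `phi_df` should give the residual degrees of freedom of that scope.
#' The test statistic is `F = (D_null - D_fit) / phi`, referred to
#' `F(1, phi_df)`; with `phi_override = 1` and `phi_df = Inf` this reduces
#' to the binomial likelihood-ratio chi-square test.
#'
#' Boundary fits (pooled rate 0 or 1) are handled by clipping the link at
#' `logit(1e-8)` and flagging the result.
#'
#' @param successes,totals integer vectors, one element per ear;
#'   `0 <= successes <= totals`, `totals > 0`.
#' @param null_rate null success rate, default Mendelian 0.5.
#' @param phi_override optional externally pooled dispersion; required when
#'   only a single ear is available.
#' @param phi_df residual degrees of freedom associated with the dispersion
#'   estimate; defaults to `k - 1`, or `Inf` when `phi_override` is given
#'   without an explicit value.
#'
#' @return A list with components `fit` (class `"qb_fit"`: `coefficients`
#'   on the logit scale, `fitted_rate`, `deviance`, `null_deviance`,
#'   `dispersion_phi`, `residual_df`, `boundary`) and `test` (a
#'   [test_result] whose estimate is the fitted rate).
#' @examples
#' quasibinomial_test(c(50, 50, 50), c(100, 100, 100))
#' @export
quasibinomial_test <- function(successes, totals, null_rate = 0.5,
                               phi_override = NULL, phi_df = NULL) {
  stopifnot(length(successes) == length(totals), length(totals) >= 1,
            all(totals > 0), all(successes >= 0), all(successes <= totals),
            null_rate > 0, null_rate < 1)
  k <- length(successes)
  rate <- sum(successes) / sum(totals)

  eps <- 1e-8
  boundary <- rate <= 0 || rate >= 1
  mu <- min(max(rate, eps), 1 - eps)

  d_fit <- binomial_deviance(successes, totals, mu)
  d_null <- binomial_deviance(successes, totals, null_rate)

  if (is.null(phi_override)) {
    if (k < 2)
      stop("dispersion is inestimable from a single ear; supply phi_override")
    phi <- sum((successes - totals * mu)^2 / (totals * mu * (1 - mu))) / (k - 1)
    if (is.null(phi_df)) phi_df <- k - 1
  } else {
    stopifnot(phi_override > 0)
    phi <- phi_override
    if (is.null(phi_df)) phi_df <- Inf
  }

  drop_dev <- max(d_null - d_fit, 0)
  if (drop_dev == 0) {
    fstat <- 0
    p <- 1
  } else {
    fstat <- drop_dev / max(phi, eps)
    p <- stats::pf(fstat, 1, phi_df, lower.tail = FALSE)
  }

  fit <- structure(
    list(coefficients = c(`(Intercept)` = stats::qlogis(mu)),
         fitted_rate = rate, deviance = d_fit, null_deviance = d_null,
         dispersion_phi = phi, residual_df = k - 1L, boundary = boundary),
    class = "qb_fit")
  tst <- test_result(
    statistic = fstat, p_value = p, estimate = rate,
    method = "quasi-likelihood F test (quasi-binomial, logit link)",
    alternative = "two.sided",
    note = if (boundary) "boundary fit: rate at 0 or 1, link clipped")
  list(fit = fit, test = tst)
}

#' @export
print.qb_fit <- function(x, ...) {
  cat("Quasi-binomial intercept-only fit (logit link)\n")
  cat("  fitted rate :", format(x$fitted_rate), "\n")
  cat("  dispersion  :", format(x$dispersion_phi),
      " (residual df", x$residual_df, ")\n")
  cat("  deviance    :", format(x$deviance),
      " null:", format(x$null_deviance), "\n")
  if (isTRUE(x$boundary)) cat("  [boundary fit]\n")
  invisible(x)
}

#' Auxiliary two-sample and one-sample tests
#'
#' Dispatcher for the secondary tests used around the main analyses:
#' * `welch_t` -- Welch two-sample t-test with Satterthwaite degrees of
#'   freedom; args `x`, `y` (each length >= 2).
#' * `two_proportion_cc` -- two-sided test for equality of two proportions
#'   with Yates continuity correction; args `successes`, `totals`
#'   (length-2 vectors).
#' * `exact_binomial` -- exact two-sided binomial test of `k/n` against
#'   `p0`; args `k`, `n`, `p0` (default 0.5).
#'
#' @param mode one of `"welch_t"`, `"two_proportion_cc"`, `"exact_binomial"`.
#' @param ... mode-appropriate arguments (see above).
#'
#' @return A [test_result].
#' @export
auxiliary_test <- function(mode = c("welch_t", "two_proportion_cc",
                                    "exact_binomial"), ...) {
  mode <- match.arg(mode)
  args <- list(...)
  switch(mode,
    welch_t = {
      x <- args$x; y <- args$y
      if (length(x) < 2 || length(y) < 2)
        stop("welch_t requires at least 2 observations per group")
      tt <- stats::t.test(x, y, var.equal = FALSE)
      test_result(statistic = unname(tt$statistic), p_value = tt$p.value,
                  estimate = unname(diff(rev(tt$estimate))),
                  method = "Welch two-sample t-test",
                  alternative = "two.sided")
    },
    two_proportion_cc = {
      s <- args$successes; n <- args$totals
      if (length(s) != 2 || length(n) != 2)
        stop("two_proportion_cc requires exactly 2 groups")
      pt <- stats::prop.test(s, n, correct = TRUE)
      test_result(statistic = unname(pt$statistic), p_value = pt$p.value,
                  estimate = unname(diff(rev(pt$estimate))),
                  method = "2-sample test for equality of proportions with continuity correction",
                  alternative = "two.sided")
    },
    exact_binomial = {
      k <- args$k; n <- args$n
      p0 <- if (is.null(args$p0)) 0.5 else args$p0
      if (is.null(n) || n < 1) stop("exact_binomial requires n >= 1")
      bt <- stats::binom.test(k, n, p = p0)
      test_result(statistic = k, p_value = bt$p.value,
                  estimate = unname(bt$estimate),
                  method = "exact binomial test",
                  alternative = "two.sided")
    })
}
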