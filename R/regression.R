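# Regression surfaces: simple logistic fits per endpoint, the multivariate
# linear model on mRS, and distribution-free median confidence intervals.

#' Simple logistic regression of a binary endpoint on a score
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (`stats::glm`, binomial logit), with Wald standard errors and p-values.
#' Complete separation is detected up front and raised as an error naming
#' the covariate, since the MLE does not exist there.
#'
#' @param x Numeric covariate, or `NULL` for an intercept-only fit.
#' @param y Binary endpoint (0/1 or logical), both classes present.
#' @param name Covariate label used in output and error messages.
#' @return List with `term`, `estimate` (slope; intercept when `x` is
#'   `NULL`), `se`, `z`, `p_value`, `intercept`, and `n`.
#' @export
logistic_fit <- function(x = NULL, y, name = "x") {
  y <- .as_binary(y)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("endpoint has a single class; logistic fit is not estimable",
         call. = FALSE)
  }
  if (is.null(x)) {
    fit <- stats::glm(y ~ 1, family = stats::binomial())
    s <- summary(fit)$coefficients
    return(list(term = "(Intercept)", estimate = unname(s[1, 1]),
                se = unname(s[1, 2]), z = unname(s[1, 3]),
                p_value = unname(s[1, 4]), intercept = unname(s[1, 1]),
                n = length(y)))
  }
  .check_numeric(x, name)
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    stop("complete separation on covariate '", name,
         "': logistic MLE does not exist", call. = FALSE)
  }
  fit <- stats::glm(y ~ x, family = stats::binomial())
  if (!fit$converged) {
    stop("logistic fit for covariate '", name, "' did not converge",
         call. = FALSE)
  }
  s <- summary(fit)$coefficients
  list(term = name, estimate = unname(s[2, 1]), se = unname(s[2, 2]),
       z = unname(s[2, 3]), p_value = unname(s[2, 4]),
       intercept = unname(s[1, 1]), n = length(y))
}

#' Multivariate linear regression table
#'
#' Ordinary least squares of a continuous/ordinal outcome on a covariate
#' set, reported as a clinical regression table: estimate, standard error,
#' 95% CI (t critical value), |t| and two-sided p per covariate.  A
#' rank-deficient design is an error naming the collinear columns.
#'
#' @param data Data frame containing outcome and covariates.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level, default 0.95.
#' @return A data frame with one row per model term (intercept first):
#'   `term`, `estimate`, `se`, `ci_low`, `ci_high`, `t_abs`, `p_value`.
#' @export
ols_multivariate <- function(data, outcome, covariates, conf_level = 0.95) {
  need <- c(outcome, covariates)
  absent <- setdiff(need, names(data))
  if (length(absent) > 0) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(covariates, response = outcome)
  mm <- stats::model.matrix(fml, data = data)
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(mm) <= ncol(mm)) {
    stop("need more observations than model terms", call. = FALSE)
  }
  fit <- stats::lm(fml, data = data)
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  data.frame(
    term = rownames(s),
    estimate = unname(s[, 1]),
    se = unname(s[, 2]),
    ci_low = unname(ci[, 1]),
    ci_high = unname(ci[, 2]),
    t_abs = abs(unname(s[, 3])),
    p_value = unname(s[, 4]),
    row.names = NULL
  )
}

#' Sample median with a distribution-free confidence interval
#'
#' The interval is built from order statistics: the widest symmetric pair
#' of ranks is narrowed to the smallest pair whose binomial coverage
#' probability reaches the requested level (exact, no distributional
#' assumption).
#'
#' @param values Numeric vector, length >= 1.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `median`, `ci_low`, `ci_high`, `conf_level`,
#'   `method`.
#' @export
median_with_ci <- function(values, conf_level = 0.95) {
  .check_numeric(values, "values")
  n <- length(values)
  s <- sort(values)
  med <- stats::median(values)
  if (n == 1) {
    return(list(median = med, ci_low = s[1], ci_high = s[1],
                conf_level = conf_level, method = "order-statistic-binomial"))
  }
  # smallest symmetric order-statistic pair with coverage >= conf_level
  l <- stats::qbinom((1 - conf_level) / 2, n, 0.5)
  repeat {
    lo <- max(1, l); hi <- min(n, n - l + 1)
    coverage <- stats::pbinom(hi - 1, n, 0.5) - stats::pbinom(lo - 1, n, 0.5)
    if (coverage >= conf_level || l <= 0) break
    l <- l - 1
  }
  list(median = med, ci_low = s[max(1, l)], ci_high = s[min(n, n - l + 1)],
       conf_level = conf_level, method = "order-statistic-binomial")
}
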