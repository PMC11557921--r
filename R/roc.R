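# ROC / cutoff / 2x2 machinery for dichotomous endpoints.

#' Dichotomize the modified Rankin Scale
#'
#' @param mrs Integer mRS values (0-6).
#' @return Logical: `TRUE` when the outcome is favorable (mRS <= 2).
#' @export
dichotomize_outcome <- function(mrs) {
  .check_range(mrs, 0, 6, "mrs")
  mrs <= 2
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the rank (Wilcoxon/Mann-Whitney) statistic: the probability
#' that a random positive outranks a random negative, ties counted 0.5,
#' which equals the trapezoidal area under the empirical ROC curve.  The
#' confidence interval uses the Hanley-McNeil normal approximation and the
#' p-value tests AUC = 0.5 on the same standard error.
#'
#' @param scores Numeric score per subject (higher = more likely positive).
#' @param labels Binary endpoint (0/1 or logical); both classes required.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `roc_result`: `thresholds` (unique scores,
#'   ascending), `sensitivity` and `fpr` at the rule score > threshold,
#'   `auc`, `auc_se`, `auc_ci_low`, `auc_ci_high`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  .check_numeric(scores, "scores")
  labels <- .as_binary(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both endpoint classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # Hanley-McNeil
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- if (se > 0) (auc - 0.5) / se else Inf
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] > t), numeric(1))
  structure(list(
    thresholds = thr, sensitivity = sens, fpr = fpr,
    auc = auc, auc_se = se,
    auc_ci_low = max(0, auc - zc * se), auc_ci_high = min(1, auc + zc * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    conf_level = conf_level, ci_method = "hanley-mcneil",
    n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%.0f%% CI %.3f-%.3f, %s), n+ = %d, n- = %d\n",
              x$auc, 100 * x$conf_level, x$auc_ci_low, x$auc_ci_high,
              format_p(x$p_value), x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Returns the threshold maximizing Youden's J = sensitivity +
#' specificity - 1 under the rule "positive iff score > cutoff"; ties are
#' broken toward the lower threshold.
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @return The selected cutoff (a value of `roc$thresholds`).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  # J compared on exact integer counts so true ties break toward the
  # lowest threshold (which.max takes the first maximizer)
  tp <- round(roc$sensitivity * roc$n_pos)
  fp <- round(roc$fpr * roc$n_neg)
  j_scaled <- tp * roc$n_neg - fp * roc$n_pos
  roc$thresholds[which.max(j_scaled)]
}

#' Two-by-two table at a cutoff
#'
#' Subjects are called test-positive when score > cutoff (strict).
#'
#' @param scores Numeric scores.
#' @param labels Binary endpoint.
#' @param cutoff Finite numeric cutoff.
#' @return An object of class `two_by_two` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
two_by_two <- function(scores, labels, cutoff) {
  .check_numeric(scores, "scores")
  labels <- .as_binary(labels)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  pos <- scores > cutoff
  structure(list(
    tp = sum(pos & labels == 1), fp = sum(pos & labels == 0),
    fn = sum(!pos & labels == 1), tn = sum(!pos & labels == 0),
    cutoff = cutoff
  ), class = "two_by_two")
}

#' Diagnostic metrics from a 2x2 table
#'
#' @param t A `two_by_two` object (or list with `tp`, `fp`, `fn`, `tn`).
#' @return A list with `sensitivity`, `specificity`, `ppv`, `npv` and an
#'   `undefined` character vector naming metrics whose denominator is zero
#'   (those metrics are `NA`).
#' @export
diagnostic_metrics <- function(t) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    sensitivity = ratio(t$tp, t$tp + t$fn),
    specificity = ratio(t$tn, t$tn + t$fp),
    ppv = ratio(t$tp, t$tp + t$fp),
    npv = ratio(t$tn, t$tn + t$fn)
  )
  out$undefined <- names(out)[vapply(out, is.na, logical(1))]
  out
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (tp * tn) / (fp * fn), with the Woolf logit interval
#' exp(ln OR +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn)) and a Wald p-value
#' on ln OR.  When any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied and flagged.  A table with an empty
#' margin (whole row or column zero) has no estimable OR and is returned
#' as undefined.
#'
#' @param t A `two_by_two` object.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`,
#'   `haldane_corrected`, `undefined`.
#' @export
odds_ratio <- function(t, conf_level = 0.95) {
  cells <- c(t$tp, t$fp, t$fn, t$tn)
  if (any(cells < 0)) stop("2x2 cells must be non-negative", call. = FALSE)
  degenerate <- (t$tp + t$fp == 0) || (t$fn + t$tn == 0) ||
                (t$tp + t$fn == 0) || (t$fp + t$tn == 0)
  if (degenerate) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, haldane_corrected = FALSE,
                undefined = TRUE))
  }
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    or = exp(lor),
    ci_low = exp(lor - zc * se), ci_high = exp(lor + zc * se),
    p_value = 2 * stats::pnorm(-abs(lor / se)),
    haldane_corrected = haldane, undefined = FALSE
  )
}

#' Format a p-value the way clinical tables print it
#'
#' @param p A p-value.
#' @param digits Decimal places, default 4.
#' @return `"<0.0001"` for values below 1e-4, otherwise the rounded value
#'   prefixed `"p = "`-free (plain number as character).
#' @export
format_p <- function(p, digits = 4) {
  ifelse(p < 1e-4, "<0.0001", formatC(round(p, digits), format = "fg"))
}

.as_binary <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
    stop("labels must be binary (0/1 or logical) without missing values",
         call. = FALSE)
  }
  labels
}
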