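# Scores are oriented so that HIGHER score = more evidence for the
# positive class. For deficiency screening the natural score is the raw
# T/C ratio, or equivalently the negated predicted concentration.

check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels))
    lfa_error("scores and labels must have equal length", "lfa_input_error")
  labels <- as.logical(labels)
  if (any(is.na(labels)) || any(!is.finite(scores)))
    lfa_error("scores must be finite and labels binary", "lfa_input_error")
  if (!any(labels) || all(labels))
    lfa_error("ROC undefined: need at least one subject in each class",
              "lfa_roc_error")
  labels
}

# Tie-corrected Mann-Whitney AUC via midranks (ties count 1/2).
auc_rank <- function(scores, labels) {
  m <- sum(labels)
  n <- sum(!labels)
  r <- rank(scores)                       # midranks
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC curve
#'
#' Sweeps every distinct score as a threshold (prediction positive when
#' `score >= threshold`), grouping ties so there is one vertex per distinct
#' score. The curve starts at (0, 0) and ends at (1, 1); its trapezoidal
#' area equals the tie-corrected Mann-Whitney AUC.
#'
#' @param scores Numeric vector; higher = more evidence for the positive
#'   class.
#' @param labels Binary vector (logical, or coercible); `TRUE` = positive.
#' @return Data frame with columns `threshold` (`Inf` for the (0,0)
#'   vertex), `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_roc_input(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' DeLong AUC with variance and confidence interval
#'
#' Nonparametric AUC (the Mann-Whitney two-sample statistic, ties counted
#' one half) with the DeLong structural-components variance estimator:
#' with positives X_i and negatives Y_j and
#' `psi(X, Y) = 1\[X > Y\] + 0.5 * 1\[X == Y\]`, the components are
#' `V10_i = mean_j psi(X_i, Y_j)` and `V01_j = mean_i psi(X_i, Y_j)`, and
#' `var(AUC) = var(V10)/m + var(V01)/n`. The 95% CI is the normal
#' approximation `auc +/- 1.96 * sqrt(var)` truncated to \[0, 1\].
#'
#' @inheritParams roc_curve
#' @return An object of class `roc_result`: list with `auc`, `variance`
#'   (`NA` unless both classes have >= 2 subjects), `ci_95`, `n_pos`,
#'   `n_neg`, `curve` (the [roc_curve()] data frame) and `method`.
#' @export
auc_delong <- function(scores, labels) {
  labels <- check_roc_input(scores, labels)
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  v10 <- vapply(x, function(xi)
    (sum(y < xi) + 0.5 * sum(y == xi)) / n, numeric(1))
  v01 <- vapply(y, function(yj)
    (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
  auc <- mean(v10)
  variance <- if (m >= 2 && n >= 2)
    stats::var(v10) / m + stats::var(v01) / n else NA_real_
  ci <- if (is.na(variance)) c(NA_real_, NA_real_) else
    pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * sqrt(variance)))
  structure(list(auc = auc, variance = variance, ci_95 = ci,
                 n_pos = m, n_neg = n,
                 curve = roc_curve(scores, labels),
                 method = "delong"),
            class = "roc_result")
}

#' Stratified bootstrap AUC
#'
#' Resamples subjects within each class, recomputing the tie-corrected AUC
#' each iteration; reports the bootstrap mean and the percentile 95% CI.
#' Provided alongside the closed-form DeLong variance as an alternative
#' uncertainty estimate for small cohorts.
#'
#' @inheritParams roc_curve
#' @param iterations Number of bootstrap resamples (>= 1).
#' @param seed RNG seed for reproducibility.
#' @return A `roc_result` with `auc` (bootstrap mean), `ci_95`
#'   (percentile), `auc_observed`, `bootstrap_iterations` and `seed`.
#' @export
auc_bootstrap <- function(scores, labels, iterations = 2000, seed = NULL) {
  labels <- check_roc_input(scores, labels)
  if (!is_scalar_number(iterations) || iterations < 1)
    lfa_error("iterations must be >= 1", "lfa_input_error")
  iterations <- as.integer(iterations)
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  lab <- c(rep(TRUE, m), rep(FALSE, n))
  draws <- with_optional_seed(seed, vapply(seq_len(iterations), function(i) {
    auc_rank(c(x[sample.int(m, m, replace = TRUE)],
               y[sample.int(n, n, replace = TRUE)]), lab)
  }, numeric(1)))
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(list(auc = mean(draws), ci_95 = ci,
                 auc_observed = auc_rank(scores, labels),
                 variance = stats::var(draws),
                 n_pos = m, n_neg = n,
                 curve = roc_curve(scores, labels),
                 bootstrap_iterations = iterations, seed = seed,
                 method = "bootstrap"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%s; %d pos / %d neg)\n",
              x$auc, x$method, x$n_pos, x$n_neg))
  if (!is.null(x$ci_95) && !any(is.na(x$ci_95)))
    cat(sprintf("  95%% CI [%.4f, %.4f]\n", x$ci_95[1], x$ci_95[2]))
  invisible(x)
}

#' Diagnostic accuracy
#'
#' The proportion of correctly classified subjects among all subjects,
#' reported both as a fraction and with the exact rational count.
#'
#' @param reference_labels,predicted_labels Equal-length, non-empty label
#'   vectors (any type comparable with `==`).
#' @return List with `n_correct`, `n_total`, `accuracy` (fraction),
#'   `percent` and `exact` (e.g. `"19/21"`).
#' @export
diagnostic_accuracy <- function(reference_labels, predicted_labels) {
  if (length(reference_labels) != length(predicted_labels))
    lfa_error("label vectors must have equal length", "lfa_input_error")
  if (length(reference_labels) == 0)
    lfa_error("empty label vectors", "lfa_input_error")
  correct <- sum(as.character(reference_labels) ==
                   as.character(predicted_labels))
  total <- length(reference_labels)
  list(n_correct = correct, n_total = total,
       accuracy = correct / total,
       percent = 100 * correct / total,
       exact = sprintf("%d/%d", correct, total))
}

#' Root mean square error of predicted concentrations
#'
#' @param reference_conc,predicted_conc Equal-length, non-empty numeric
#'   vectors in nmol/L.
#' @return RMSE in nmol/L.
#' @export
rmse <- function(reference_conc, predicted_conc) {
  if (length(reference_conc) != length(predicted_conc))
    lfa_error("vectors must have equal length", "lfa_input_error")
  if (length(reference_conc) == 0)
    lfa_error("empty input", "lfa_input_error")
  if (any(!is.finite(reference_conc)) || any(!is.finite(predicted_conc)))
    lfa_error("concentrations must be finite", "lfa_input_error")
  sqrt(mean((predicted_conc - reference_conc)^2))
}

#' Evaluate a cohort at a guideline cutoff
#'
#' Convenience wrapper producing the full diagnostic report for a cohort of
#' (reference concentration, predicted concentration) pairs: DeLong and
#' bootstrap AUC at the cutoff, diagnostic accuracy of the dichotomized
#' calls, and RMSE. The ROC score is the negated predicted concentration
#' (lower predicted concentration = more evidence of deficiency); set
#' `scores` to use a different scale such as the raw T/C ratio.
#'
#' @param reference_conc,predicted_conc Numeric vectors in nmol/L.
#' @param cutoff Deficiency cutoff in nmol/L (positive class: reference
#'   below the cutoff).
#' @param scores Optional explicit ROC scores (higher = more deficient);
#'   default `-predicted_conc`.
#' @param iterations Bootstrap iterations.
#' @param seed RNG seed for the bootstrap.
#' @return List with `cutoff`, `n`, `delong`, `bootstrap`, `accuracy`,
#'   `rmse_nmol_L`.
#' @export
evaluate_cohort <- function(reference_conc, predicted_conc, cutoff = 50,
                            scores = NULL, iterations = 2000, seed = NULL) {
  if (length(reference_conc) != length(predicted_conc))
    lfa_error("vectors must have equal length", "lfa_input_error")
  labels <- binarize(reference_conc, cutoff) == "below"
  if (is.null(scores)) scores <- -predicted_conc
  list(cutoff = cutoff,
       n = length(reference_conc),
       delong = auc_delong(scores, labels),
       bootstrap = auc_bootstrap(scores, labels, iterations, seed),
       accuracy = diagnostic_accuracy(binarize(reference_conc, cutoff),
                                      binarize(predicted_conc, cutoff)),
       rmse_nmol_L = rmse(reference_conc, predicted_conc))
}
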