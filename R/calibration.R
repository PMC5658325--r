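#' Calibration model constructors
#'
#' A calibration model maps 25(OH)D3 concentration (nmol/L) to the measured
#' test/control (T/C) ratio. Two families are supported:
#'
#' * **linear**: `T/C = a * conc + b`. For a competitive assay the slope `a`
#'   is negative (more analyte, fainter test line).
#' * **four-parameter logistic (4PL)**:
#'   `T/C = d + (a - d) / (1 + (conc / c)^b)` with upper asymptote `a`
#'   (response at zero concentration), slope exponent `b > 0`, inflection
#'   concentration `c > 0` (nmol/L) and lower asymptote `d`. With `a > d`
#'   the curve is strictly decreasing, so inversion is unique.
#'
#' @param a For `linear_calibration`, the slope (T/C per nmol/L); for
#'   `fourpl_calibration`, the upper asymptote (T/C at zero concentration).
#' @param b For `linear_calibration`, the intercept (T/C at 0 nmol/L); for
#'   `fourpl_calibration`, the slope exponent (must be > 0).
#' @param c4 Inflection concentration of the 4PL in nmol/L (must be > 0).
#' @param d Lower asymptote of the 4PL (must satisfy `d < a`).
#' @return An object of class `linear_calibration` or `fourpl_calibration`
#'   (both inherit from `calibration_model`).
#' @examples
#' # As reported for the assay in standard buffer and in serum calibrators:
#' linear_calibration(a = -0.0251, b = 3.983)
#' fourpl_calibration(a = 2.81, b = 2.63, c4 = 26.2, d = 1.52)
#' @export
linear_calibration <- function(a, b) {
  if (!is_scalar_number(a) || !is_scalar_number(b))
    lfa_error("linear calibration parameters must be finite scalars",
              "lfa_model_error")
  if (a == 0)
    lfa_error("linear calibration slope a must be non-zero (invertibility)",
              "lfa_model_error")
  structure(list(a = a, b = b),
            class = c("linear_calibration", "calibration_model"))
}

#' @rdname linear_calibration
#' @export
fourpl_calibration <- function(a, b, c4, d) {
  for (p in list(a, b, c4, d))
    if (!is_scalar_number(p))
      lfa_error("4PL parameters must be finite scalars", "lfa_model_error")
  if (c4 <= 0)
    lfa_error("4PL inflection concentration c must be > 0", "lfa_model_error")
  if (b <= 0)
    lfa_error("4PL slope exponent b must be > 0", "lfa_model_error")
  if (a <= d)
    lfa_error("4PL requires a > d for a decreasing competitive curve",
              "lfa_model_error")
  structure(list(a = a, b = b, c = c4, d = d),
            class = c("fourpl_calibration", "calibration_model"))
}

#' @export
print.calibration_model <- function(x, ...) {
  if (inherits(x, "linear_calibration")) {
    cat(sprintf("Linear calibration: T/C = %g * [25(OH)D3] + %g\n", x$a, x$b))
  } else {
    cat(sprintf(
      "4PL calibration: T/C = %g + (%g - %g)/(1 + ([25(OH)D3]/%g)^%g)\n",
      x$d, x$a, x$d, x$c, x$b))
  }
  invisible(x)
}

#' Forward prediction: concentration to T/C ratio
#'
#' Evaluates a calibration model at the given concentrations. This single
#' implementation is shared by the simulator's forward response
#' ([concentration_to_tc()] is an alias).
#'
#' @param model A `calibration_model`.
#' @param conc Numeric vector of concentrations in nmol/L (all >= 0).
#' @return Numeric vector of T/C ratios. For the 4PL at `conc = 0` the value
#'   is exactly the upper asymptote `a` (the `b > 0` limit convention).
#' @export
predict_tc <- function(model, conc) {
  UseMethod("predict_tc")
}

check_conc_domain <- function(conc) {
  if (!is.numeric(conc) || any(!is.finite(conc)))
    lfa_error("concentrations must be finite numbers", "lfa_domain_error")
  if (any(conc < 0))
    lfa_error("negative concentration is outside the assay domain",
              "lfa_domain_error")
}

#' @export
predict_tc.linear_calibration <- function(model, conc) {
  check_conc_domain(conc)
  model$a * conc + model$b
}

#' @export
predict_tc.fourpl_calibration <- function(model, conc) {
  check_conc_domain(conc)
  # (0/c)^b == 0 for b > 0, so conc = 0 yields a exactly.
  model$d + (model$a - model$d) / (1 + (conc / model$c)^model$b)
}

#' Inverse prediction: T/C ratio to concentration
#'
#' Inverts a calibration model. Linear: `conc = (tc - b)/a`; negative
#' solutions are clamped to 0 and flagged. 4PL:
#' `conc = c * ((a - d)/(tc - d) - 1)^(1/b)`, defined for `tc` strictly
#' between the asymptotes `d` and `a`; values outside that open interval are
#' censored rather than raised as errors, matching assay-reporting practice
#' ("< lower limit" / "> upper limit" style results).
#'
#' @param model A `calibration_model`.
#' @param tc Numeric vector of T/C ratios.
#' @return A data frame with columns `tc`, `conc` (nmol/L; 0 for
#'   below-range censoring, `NA` for above-range censoring where no finite
#'   value exists) and `censor`, a factor with levels
#'   `none`, `below_range`, `above_range`. For a competitive (decreasing)
#'   model, `below_range` means the signal implies a concentration below 0
#'   and `above_range` means the signal is at or past the lower asymptote,
#'   i.e. beyond the upper quantifiable limit.
#' @export
invert_tc <- function(model, tc) {
  UseMethod("invert_tc")
}

censor_levels <- c("none", "below_range", "above_range")

#' @export
invert_tc.linear_calibration <- function(model, tc) {
  if (!is.numeric(tc) || any(!is.finite(tc)))
    lfa_error("tc must be finite", "lfa_domain_error")
  conc <- (tc - model$b) / model$a
  censor <- rep("none", length(tc))
  neg <- conc < 0
  conc[neg] <- 0
  # with a < 0 a negative solution means tc above the zero-dose response
  censor[neg] <- if (model$a < 0) "below_range" else "above_range"
  data.frame(tc = tc, conc = conc,
             censor = factor(censor, levels = censor_levels))
}

#' @export
invert_tc.fourpl_calibration <- function(model, tc) {
  if (!is.numeric(tc) || any(!is.finite(tc)))
    lfa_error("tc must be finite", "lfa_domain_error")
  conc <- rep(NA_real_, length(tc))
  censor <- rep("none", length(tc))
  inside <- tc > model$d & tc < model$a
  conc[inside] <- model$c *
    ((model$a - model$d) / (tc[inside] - model$d) - 1)^(1 / model$b)
  hi <- tc >= model$a            # at/above upper asymptote: conc <= 0
  conc[hi] <- 0
  censor[hi] <- "below_range"
  lo <- tc <= model$d            # at/below lower asymptote: beyond range
  censor[lo] <- "above_range"
  data.frame(tc = tc, conc = conc,
             censor = factor(censor, levels = censor_levels))
}

aggregate_points <- function(conc, tc, aggregate) {
  if (aggregate == "mean") {
    m <- tapply(tc, conc, mean)
    list(conc = as.numeric(names(m)), tc = as.numeric(m))
  } else {
    list(conc = conc, tc = tc)
  }
}

check_points <- function(conc, tc) {
  if (length(conc) != length(tc))
    lfa_error("conc and tc must have equal length", "lfa_input_error")
  if (!is.numeric(conc) || !is.numeric(tc) ||
      any(!is.finite(conc)) || any(!is.finite(tc)))
    lfa_error("calibration points must be finite numbers", "lfa_input_error")
}

fit_diagnostics <- function(observed, fitted, converged = TRUE) {
  res <- observed - fitted
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  list(r_squared = r2,
       residuals = res,
       n_points = length(observed),
       converged = converged,
       rmse_tc = sqrt(mean(res^2)))
}

#' Fit a linear calibration by ordinary least squares
#'
#' @param conc,tc Paired numeric vectors of concentration (nmol/L) and
#'   measured T/C ratio.
#' @param aggregate `"mean"` (default) averages replicate T/C values at each
#'   concentration before fitting; `"none"` fits per-strip points.
#' @return A list of class `calibration_fit` with elements `model`
#'   (a [linear_calibration()]) and `diagnostics` (R-squared, residuals,
#'   `n_points`, `converged`, `rmse_tc`).
#' @examples
#' conc <- seq(0, 150, by = 10)
#' fit <- fit_linear(conc, -0.075 * conc + 5.689)
#' fit$model$a      # -0.075 recovered exactly on noiseless points
#' @export
fit_linear <- function(conc, tc, aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  check_points(conc, tc)
  pts <- aggregate_points(conc, tc, aggregate)
  if (length(unique(pts$conc)) < 2)
    lfa_error("need at least 2 distinct concentrations for a linear fit",
              "lfa_singular_fit_error")
  fit <- stats::lm(y ~ x, data = data.frame(x = pts$conc, y = pts$tc))
  cf <- stats::coef(fit)
  model <- linear_calibration(a = unname(cf[2]), b = unname(cf[1]))
  structure(list(model = model,
                 diagnostics = fit_diagnostics(pts$tc, stats::fitted(fit)),
                 points = pts),
            class = "calibration_fit")
}

#' Fit a four-parameter logistic calibration
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) for `tc = d + (a - d)/(1 + (conc/c)^b)`.
#' Initialisation: `a0 = max(tc)`, `d0 = min(tc)`, `c0 = median(conc > 0)`,
#' `b0 = 1`; bounds enforce `c > 0` and `b > 0`. Non-convergence or a
#' degenerate input (for instance points on a straight line) is reported
#' through `diagnostics$converged = FALSE`, never as a crash.
#'
#' @inheritParams fit_linear
#' @return A `calibration_fit`; `model` is a [fourpl_calibration()] when the
#'   optimiser converged to an admissible parameter set, otherwise an
#'   unclassed parameter list with `diagnostics$converged = FALSE`.
#' @examples
#' conc <- c(0, 5, 10, 15, 20, 30, 40, 50, 60, 75, 90, 105, 120, 135, 150, 25)
#' tc <- predict_tc(fourpl_calibration(2.81, 2.63, 26.2, 1.52), conc)
#' fit_4pl(conc, tc)$model$c     # inflection recovered at 26.2
#' @export
fit_4pl <- function(conc, tc, aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  check_points(conc, tc)
  pts <- aggregate_points(conc, tc, aggregate)
  if (length(unique(pts$conc)) < 5)
    lfa_error("need at least 5 distinct concentrations for a 4PL fit",
              "lfa_singular_fit_error")
  dat <- data.frame(x = pts$conc, y = pts$tc)
  pos <- dat$x[dat$x > 0]
  start <- list(a = max(dat$y), d = min(dat$y),
                c = if (length(pos)) stats::median(pos) else 1, b = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (x / c)^b),
      data = dat, start = start,
      lower = c(a = -Inf, d = -Inf, c = .Machine$double.eps, b = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    diag <- fit_diagnostics(pts$tc, rep(mean(pts$tc), length(pts$tc)),
                            converged = FALSE)
    return(structure(list(model = c(start, note = conditionMessage(fit)),
                          diagnostics = diag, points = pts),
                     class = "calibration_fit"))
  }
  cf <- as.list(stats::coef(fit))
  converged <- isTRUE(fit$convInfo$isConv)
  model <- tryCatch(
    fourpl_calibration(a = cf$a, b = cf$b, c4 = cf$c, d = cf$d),
    lfa_error = function(e) {          # inadmissible optimum (e.g. a <= d)
      converged <<- FALSE
      cf
    })
  diag <- fit_diagnostics(pts$tc, as.numeric(stats::fitted(fit)),
                          converged = converged)
  structure(list(model = model, diagnostics = diag, points = pts),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (inherits(x$model, "calibration_model")) print(x$model)
  cat(sprintf("  n = %d, R^2 = %.4f, RMSE(T/C) = %.4g, converged = %s\n",
              x$diagnostics$n_points, x$diagnostics$r_squared,
              x$diagnostics$rmse_tc, x$diagnostics$converged))
  invisible(x)
}

#' Replicate precision (coefficient of variation)
#'
#' Groups replicate T/C measurements by nominal concentration and reports
#' the per-level coefficient of variation, `100 * sd / mean`, with the
#' sample (n - 1) standard deviation.
#'
#' @param conc Numeric vector of nominal concentrations.
#' @param tc Numeric vector of replicate T/C values, parallel to `conc`.
#' @return Data frame with one row per concentration level: `conc`, `n`,
#'   `mean`, `sd`, `cv_percent` (`NA` with `undefined = TRUE` when the mean
#'   is not positive or fewer than 2 replicates exist).
#' @export
replicate_cv <- function(conc, tc) {
  check_points(conc, tc)
  levels <- sort(unique(conc))
  rows <- lapply(levels, function(cl) {
    v <- tc[conc == cl]
    m <- mean(v)
    s <- if (length(v) >= 2) stats::sd(v) else NA_real_
    ok <- length(v) >= 2 && m > 0
    data.frame(conc = cl, n = length(v), mean = m, sd = s,
               cv_percent = if (ok) 100 * s / m else NA_real_,
               undefined = !ok)
  })
  do.call(rbind, rows)
}

#' Serialize / restore a calibration as JSON
#'
#' The document carries the model family, parameters, fit diagnostics, the
#' valid (fitted) concentration range and a batch identifier; calibrations
#' are batch-specific, so predictions should only be made with a calibration
#' from the same strip batch.
#'
#' @param fit A `calibration_fit` (or a bare `calibration_model`).
#' @param path File to write / read.
#' @param batch_id Free-text batch identifier stored in the document.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `calibration_fit`.
#' @export
write_calibration <- function(fit, path, batch_id = "unspecified") {
  if (inherits(fit, "calibration_model"))
    fit <- structure(list(model = fit, diagnostics = NULL, points = NULL),
                     class = "calibration_fit")
  if (!inherits(fit$model, "calibration_model"))
    lfa_error("refusing to serialize a non-converged calibration",
              "lfa_model_error")
  family <- if (inherits(fit$model, "linear_calibration")) "linear" else "4pl"
  doc <- list(
    family = family,
    parameters = unclass(fit$model),
    diagnostics = fit$diagnostics,
    conc_range = if (!is.null(fit$points)) range(fit$points$conc) else NULL,
    batch_id = batch_id)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    lfa_error(sprintf("calibration file not found: %s", path),
              "lfa_config_error")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- doc$parameters
  model <- switch(doc$family,
    linear = linear_calibration(a = p$a, b = p$b),
    `4pl` = fourpl_calibration(a = p$a, b = p$b, c4 = p$c, d = p$d),
    lfa_error(sprintf("unknown calibration family '%s'", doc$family),
              "lfa_config_error"))
  structure(list(model = model, diagnostics = doc$diagnostics,
                 points = NULL, conc_range = doc$conc_range,
                 batch_id = doc$batch_id),
            class = "calibration_fit")
}

#' Reference calibrations reported for the vitamin D3 assay
#'
#' Named parameter sets for the assay in different matrices: the
#' standard-buffer line, the serum-calibrator 4PL, the human-serum line and
#' the finger-stick-blood line. Useful as simulator forward models and as
#' worked-example inputs.
#'
#' @return Named list of `calibration_model` objects:
#'   `standard_linear`, `calibrator_4pl`, `serum_linear`, `blood_linear`.
#' @export
vitd_reference_calibrations <- function() {
  list(
    standard_linear = linear_calibration(a = -0.0251, b = 3.983),
    calibrator_4pl  = fourpl_calibration(a = 2.81, b = 2.63,
                                         c4 = 26.2, d = 1.52),
    serum_linear    = linear_calibration(a = -0.075, b = 5.689),
    blood_linear    = linear_calibration(a = -0.033, b = 2.9925))
}
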