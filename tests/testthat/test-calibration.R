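test_that("linear fits recover generating parameters exactly", {
  conc <- seq(0, 70, by = 10)
  fit <- fit_linear(conc, -0.075 * conc + 5.689)
  expect_equal(fit$model$a, -0.075, tolerance = 1e-12)
  expect_equal(fit$model$b, 5.689, tolerance = 1e-12)
  expect_equal(fit$diagnostics$r_squared, 1)
  # two points interpolate perfectly
  f2 <- fit_linear(c(10, 50), c(3, 1))
  expect_equal(f2$diagnostics$r_squared, 1)
  expect_error(fit_linear(rep(25, 4), c(1, 2, 3, 4)),
               class = "lfa_singular_fit_error")
})

test_that("4PL fits recover generating parameters on noiseless data", {
  truth <- ref_cal$calibrator_4pl
  tc <- predict_tc(truth, calibrator_design)
  fit <- fit_4pl(calibrator_design, tc)
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$model$a, truth$a, tolerance = 1e-4)
  expect_equal(fit$model$b, truth$b, tolerance = 1e-4)
  expect_equal(fit$model$c, truth$c, tolerance = 1e-4)
  expect_equal(fit$model$d, truth$d, tolerance = 1e-4)
  expect_equal(fit$diagnostics$r_squared, 1, tolerance = 1e-10)
})

test_that("degenerate 4PL input never crashes", {
  conc <- seq(0, 100, by = 10)
  fit <- expect_no_error(fit_4pl(conc, 3 - 0.01 * conc))
  expect_s3_class(fit, "calibration_fit")
  expect_true(is.logical(fit$diagnostics$converged))
  expect_error(fit_4pl(c(1, 2, 3), c(3, 2, 1)),
               class = "lfa_singular_fit_error")  # too few levels
})

test_that("forward prediction evaluates the stored equations", {
  expect_equal(predict_tc(ref_cal$standard_linear, 100), 1.473)
  expect_equal(predict_tc(ref_cal$calibrator_4pl, 1e7),
               1.52, tolerance = 1e-6)
  expect_equal(predict_tc(ref_cal$serum_linear, 0), 5.689)
})

test_that("inversion is exact and censors out-of-domain ratios", {
  expect_equal(invert_tc(ref_cal$standard_linear, 3.983)$conc, 0)
  inv_mid <- invert_tc(ref_cal$calibrator_4pl, 2.165)
  expect_equal(inv_mid$conc, 26.2)
  expect_equal(as.character(inv_mid$censor), "none")
  # below the lower asymptote: beyond the upper quantifiable limit
  hi <- invert_tc(ref_cal$calibrator_4pl, 1.0)
  expect_equal(as.character(hi$censor), "above_range")
  expect_true(is.na(hi$conc))
  # above the zero-dose response: clamped to 0, flagged
  lo <- invert_tc(ref_cal$serum_linear, 6.2)
  expect_equal(lo$conc, 0)
  expect_equal(as.character(lo$censor), "below_range")
})

test_that("invert is the exact inverse of predict on the valid domain", {
  set.seed(21)
  for (i in 1:25) {
    lin <- linear_calibration(a = runif(1, -0.2, -0.01), b = runif(1, 2, 6))
    x <- runif(10, 0, 100)
    expect_equal(invert_tc(lin, predict_tc(lin, x))$conc, x,
                 tolerance = 1e-9)
    pl <- fourpl_calibration(a = runif(1, 2, 6), b = runif(1, 0.5, 4),
                             c4 = runif(1, 10, 60), d = runif(1, 0.2, 1.5))
    x <- runif(10, 0.1, 150)
    expect_equal(invert_tc(pl, predict_tc(pl, x))$conc, x,
                 tolerance = 1e-9)
  }
})

test_that("4PL c is recovered within 15% under replicate noise (>= 90%)", {
  truth <- ref_cal$calibrator_4pl
  clean <- predict_tc(truth, calibrator_design)
  hits <- withr::with_seed(2024, {
    vapply(1:500, function(i) {
      conc <- rep(calibrator_design, each = 2)       # two strips per level
      tc <- rep(clean, each = 2) * rnorm(length(conc), 1, 0.05)
      fit <- fit_4pl(conc, tc)                       # mean-mode default
      is.list(fit$model) && !is.null(fit$model$c) &&
        abs(fit$model$c - truth$c) / truth$c <= 0.15
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("R-squared decreases as replicate noise grows", {
  truth <- ref_cal$calibrator_4pl
  clean <- predict_tc(truth, calibrator_design)
  r2_at <- function(cv, seed) {
    withr::with_seed(seed, {
      r2 <- vapply(1:40, function(i) {
        tc <- clean * rnorm(length(clean), 1, cv)
        fit_4pl(calibrator_design, tc)$diagnostics$r_squared
      }, numeric(1))
      mean(r2)
    })
  }
  expect_gt(r2_at(0.02, 31), r2_at(0.10, 31))
  expect_gt(r2_at(0.10, 31), r2_at(0.25, 31))
})

test_that("replicate CV matches two-point arithmetic and generative truth", {
  tab <- replicate_cv(c(100, 100), c(1.8, 2.2))
  expect_equal(tab$cv_percent, 100 * sd(c(1.8, 2.2)) / 2, tolerance = 1e-12)
  expect_equal(replicate_cv(c(5, 5, 5), c(2, 2, 2))$cv_percent, 0)
  expect_true(replicate_cv(c(1, 1), c(-2, 2))$undefined)
  co <- simulate_cohort(200, ref_cal$calibrator_4pl, conc_sampler = 40,
                        replicate_cv = 0.05, seed = 8)
  emp <- replicate_cv(co$conc, co$tc)
  expect_gt(emp$cv_percent, 4)
  expect_lt(emp$cv_percent, 6)
})

test_that("calibration JSON round-trips with diagnostics and batch id", {
  conc <- seq(0, 150, by = 10)
  fit <- fit_linear(conc, predict_tc(ref_cal$standard_linear, conc))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, path, batch_id = "batch-A")
  back <- read_calibration(path)
  expect_equal(back$model$a, fit$model$a)
  expect_equal(back$model$b, fit$model$b)
  expect_equal(back$batch_id, "batch-A")
  expect_equal(back$conc_range, c(0, 150))
  expect_error(read_calibration("no/such/file.json"),
               class = "lfa_config_error")
})
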