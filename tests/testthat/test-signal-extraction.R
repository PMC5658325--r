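test_that("crop_roi is an identity on the full frame and validates bounds", {
  img <- make_strip(1)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  expect_identical(crop_roi(img, c(0, nr, 0, nc))$pixels, img$pixels)
  expect_error(crop_roi(img, c(0, nr + 1, 0, nc)),
               class = "lfa_geometry_error")
  expect_error(crop_roi(img, c(0, 0, 0, nc)), class = "lfa_geometry_error")
  expect_error(crop_roi(img, c(5, 2, 0, nc)), class = "lfa_geometry_error")
})

test_that("cropping out the control line raises a missing-control error", {
  img <- make_strip(2.5)
  cfg <- default_config()
  # cut the frame just downstream of the test line (control centre ~ px 280)
  cfg$roi <- c(0, nrow(img$pixels), 0, 250)
  expect_error(quantify_image(img, cfg),
               class = "lfa_missing_control_error")
})

test_that("grayscale conversion uses the fixed luminance weights", {
  rgb <- array(0, dim = c(4, 25, 3))
  rgb[, , 1] <- 0.3; rgb[, , 2] <- 0.3; rgb[, , 3] <- 0.3
  expect_equal(to_grayscale(rgb)$pixels, matrix(0.3, 4, 25))
  green <- array(0, dim = c(4, 25, 3)); green[, , 2] <- 1
  expect_equal(unique(as.numeric(to_grayscale(green)$pixels)), 0.587)
  gray <- matrix(runif(100), 4, 25)
  expect_identical(to_grayscale(gray)$pixels, gray)
  expect_error(to_grayscale(array(0, dim = c(4, 25, 4))),
               class = "lfa_format_error")
})

test_that("denoise: identity at sigma 0, conservation, kernel oracle", {
  img <- make_strip(1, noise_sigma = 0.02, seed = 5)
  expect_identical(denoise(img, 0), img)
  flat <- strip_image(matrix(0.6, 10, 40))
  expect_equal(denoise(flat, 3)$pixels, flat$pixels)
  # impulse response equals the direct outer-product Gaussian kernel
  imp <- matrix(0, 21, 41); imp[11, 21] <- 1
  sm <- denoise(strip_image(imp), 1.5)$pixels
  k <- dnorm(seq(-6, 6), sd = 1.5); k <- k / sum(k)
  expect_equal(sm[5:17, 15:27], outer(k, k), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)   # unit mass preserved
})

test_that("profile collapse is the per-column median plus running median", {
  row <- seq(0.2, 0.8, length.out = 40)
  img <- strip_image(matrix(row, nrow = 6, ncol = 40, byrow = TRUE))
  expect_equal(collapse_to_profile(img, 1)$values, row)
  # a salt-corrupted row leaves the median profile unchanged
  dirty <- img
  dirty$pixels[3, ] <- 1
  expect_equal(collapse_to_profile(dirty, 5)$values,
               collapse_to_profile(img, 5)$values)
  expect_error(collapse_to_profile(img, 4), class = "lfa_config_error")
  expect_error(collapse_to_profile(img, 41), class = "lfa_config_error")
  expect_error(collapse_to_profile(strip_image(matrix(0.5, 2, 40)), 5),
               class = "lfa_format_error")
})

test_that("line detection finds both lines at the rendered centres", {
  img <- make_strip(2.5)
  prof <- collapse_to_profile(denoise(img, 2), 5)
  det <- detect_lines(prof, expected_separation_px = 80)
  expect_lte(abs(det$test$position_px - img$truth$test_center_px), 1)
  expect_lte(abs(det$control$position_px - img$truth$control_center_px), 1)
  expect_gt(det$test$depth, det$control$depth)   # tc > 1
})

test_that("flat profiles and absent test bands are handled", {
  flat <- collapse_to_profile(strip_image(matrix(0.7, 10, 200)), 1)
  expect_error(detect_lines(flat, 80), class = "lfa_missing_line_error")
  res0 <- quantify_image(make_strip(0))
  expect_equal(res0$tc_ratio, 0)
  expect_true("weak_test" %in% res0$qc_flags)
})

test_that("compute_tc is the baseline-relative depth ratio", {
  mk <- function(depth) {
    structure(list(position_px = 100, raw_min = 0.8 - depth, baseline = 0.8,
                   depth = depth, prominence = depth),
              class = "line_peak")
  }
  expect_equal(compute_tc(mk(0.2), mk(0.1))$tc_ratio, 2)
  expect_equal(compute_tc(mk(0.15), mk(0.15))$tc_ratio, 1)
  expect_error(compute_tc(mk(0.2), mk(0.01)),
               class = "lfa_invalid_test_error")
})

test_that("noiseless round trip recovers T/C to 1e-3 and is monotone", {
  grid <- seq(0.5, 5, length.out = 12)
  got <- vapply(grid, function(tc) quantify_image(make_strip(tc))$tc_ratio,
                numeric(1))
  expect_lt(max(abs(got - grid)), 1e-3)
  expect_true(all(diff(got) > 0))
})

test_that("T/C is invariant to intensity offset and scale", {
  img <- make_strip(3.1)
  base <- quantify_image(img)$tc_ratio
  shifted <- img; shifted$pixels <- img$pixels + 0.05   # no clipping
  scaled <- img; scaled$pixels <- img$pixels * 0.9
  expect_equal(quantify_image(shifted)$tc_ratio, base, tolerance = 1e-9)
  expect_equal(quantify_image(scaled)$tc_ratio, base, tolerance = 1e-9)
})

test_that("extraction is robust to pixel noise (< 5% at sigma 0.01)", {
  for (tc in c(0.5, 1.5, 3, 5)) {
    clean <- quantify_image(make_strip(tc))$tc_ratio
    noisy <- quantify_image(make_strip(tc, noise_sigma = 0.01,
                                       seed = round(100 * tc)))$tc_ratio
    expect_lt(abs(noisy - clean) / clean, 0.05)
  }
})

test_that("quantification is deterministic and carries provenance", {
  img <- make_strip(2)
  r1 <- quantify_image(img)
  r2 <- quantify_image(img)
  expect_identical(r1, r2)
  expect_equal(r1$provenance$gaussian_sigma_px, 2)
  expect_equal(r1$provenance$expected_separation_px, 80)
  expect_match(r1$provenance$config_hash, "^[0-9a-f]{32}$")
})
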