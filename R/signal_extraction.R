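#' Strip image container
#'
#' A grayscale raster of the cassette window. Rows run across the strip,
#' columns along the flow axis (increasing column index = downstream).
#' Values are on a 0-1 intensity scale regardless of the camera bit depth;
#' 8/16-bit quantisation happens only at file write time.
#'
#' @param pixels Numeric matrix with values in \[0, 1\].
#' @param pixels_per_mm Optional scale (pixels per millimetre).
#' @param truth Optional ground-truth manifest (attached by the simulator).
#' @param roi Optional record of the crop applied (0-based, half-open).
#' @return A `strip_image` object.
#' @export
strip_image <- function(pixels, pixels_per_mm = NULL, truth = NULL,
                        roi = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    lfa_error("pixels must be a numeric matrix", "lfa_format_error")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    lfa_error("pixel values must be finite and within [0, 1]",
              "lfa_format_error")
  structure(list(pixels = pixels, pixels_per_mm = pixels_per_mm,
                 truth = truth, roi = roi),
            class = "strip_image")
}

#' @export
print.strip_image <- function(x, ...) {
  cat(sprintf("strip_image: %d x %d px%s%s\n",
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$pixels_per_mm)) "" else
                sprintf(" (%g px/mm)", x$pixels_per_mm),
              if (is.null(x$truth)) "" else
                sprintf(", true T/C = %g", x$truth$tc_ratio_true)))
  invisible(x)
}

#' Crop a fixed region of interest
#'
#' The ROI comes from cassette registration (a fixed window in the imaging
#' device), not from content analysis. Coordinates are 0-based half-open
#' intervals `c(row0, row1, col0, col1)`: rows `[row0, row1)`, columns
#' `[col0, col1)`.
#'
#' @param image A `strip_image`.
#' @param roi Integer vector `c(row0, row1, col0, col1)`.
#' @return The cropped `strip_image` with the applied ROI recorded.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(image, "strip_image"))
  if (length(roi) != 4 || any(!is.finite(roi)))
    lfa_error("roi must be c(row0, row1, col0, col1)", "lfa_geometry_error")
  roi <- as.integer(roi)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nr || roi[4] > nc)
    lfa_error("roi lies outside the image bounds", "lfa_geometry_error")
  if (roi[2] <= roi[1] || roi[4] <= roi[3])
    lfa_error("roi is degenerate (zero or negative extent)",
              "lfa_geometry_error")
  out <- image
  out$pixels <- image$pixels[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4],
                             drop = FALSE]
  out$roi <- roi
  out
}

#' Convert a colour raster to grayscale
#'
#' Fixed luminance weights 0.299 R + 0.587 G + 0.114 B. Single-channel
#' input (a matrix, or an array with one plane) passes through unchanged.
#'
#' @param x A numeric matrix (grayscale) or an `h x w x 3` array in
#'   \[0, 1\].
#' @param ... Passed to [strip_image()] (e.g. `pixels_per_mm`).
#' @return A `strip_image`.
#' @export
to_grayscale <- function(x, ...) {
  if (inherits(x, "strip_image")) return(x)
  if (is.matrix(x)) return(strip_image(x, ...))
  if (is.array(x) && length(dim(x)) == 3) {
    ch <- dim(x)[3]
    if (ch == 1) return(strip_image(x[, , 1], ...))
    if (ch == 3)
      return(strip_image(0.299 * x[, , 1] + 0.587 * x[, , 2] +
                           0.114 * x[, , 3], ...))
    lfa_error(sprintf("unsupported channel count: %d (expected 1 or 3)", ch),
              "lfa_format_error")
  }
  lfa_error("input must be a matrix or a 3-channel array",
            "lfa_format_error")
}

# Separable Gaussian convolution with symmetric (reflective) boundary
# padding; kernel truncated at 4 sigma (capped so the padding fits the
# extent) and renormalised to unit sum.
gaussian_kernel <- function(sigma, max_radius = Inf) {
  r <- min(max(1L, ceiling(4 * sigma)), max_radius)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

reflect_pad <- function(v, r) {
  n <- length(v)
  c(v[r:1], v, v[n:(n - r + 1)])
}

convolve_reflect <- function(v, kernel) {
  r <- (length(kernel) - 1L) / 2L
  padded <- reflect_pad(v, r)
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  as.numeric(out[(r + 1):(r + length(v))])
}

#' Gaussian denoising of a strip image
#'
#' 2D Gaussian smoothing implemented as separable row/column convolutions
#' with reflective boundary handling; `sigma = 0` is the identity.
#'
#' @param image A `strip_image`.
#' @param gaussian_sigma_px Kernel standard deviation in pixels (>= 0).
#' @return The smoothed `strip_image` (re-clipped to \[0, 1\]).
#' @export
denoise <- function(image, gaussian_sigma_px = 2) {
  stopifnot(inherits(image, "strip_image"))
  if (!is_scalar_number(gaussian_sigma_px) || gaussian_sigma_px < 0)
    lfa_error("gaussian_sigma_px must be >= 0", "lfa_config_error")
  if (gaussian_sigma_px == 0) return(image)
  m <- image$pixels
  k_col <- gaussian_kernel(gaussian_sigma_px, max_radius = nrow(m) - 1L)
  k_row <- gaussian_kernel(gaussian_sigma_px, max_radius = ncol(m) - 1L)
  m <- apply(m, 2, convolve_reflect, kernel = k_col)    # down columns
  m <- t(apply(m, 1, convolve_reflect, kernel = k_row)) # along rows
  out <- image
  out$pixels <- pmin(pmax(m, 0), 1)
  out
}

#' Collapse a 2D strip image to a 1D intensity profile
#'
#' The per-column median across rows gives the signal along the flow axis
#' (robust to row-local defects such as dust or scratches); an optional
#' running 1D median of odd window `median_window_px` then suppresses
#' remaining along-axis speckle. `median_window_px = 1` skips that step.
#'
#' @param image A `strip_image` (at least 3 rows and 20 columns).
#' @param median_window_px Odd window length for the 1D running median.
#' @return An `intensity_profile`: list with `values`, `pixels_per_mm` and
#'   the smoothing metadata.
#' @export
collapse_to_profile <- function(image, median_window_px = 5) {
  stopifnot(inherits(image, "strip_image"))
  if (nrow(image$pixels) < 3 || ncol(image$pixels) < 20)
    lfa_error("image too small: need >= 3 rows and >= 20 columns",
              "lfa_format_error")
  w <- median_window_px
  if (!is_scalar_number(w) || w < 1 || w %% 2 == 0)
    lfa_error("median_window_px must be an odd integer >= 1",
              "lfa_config_error")
  values <- apply(image$pixels, 2, stats::median)
  if (w > length(values))
    lfa_error("median window larger than the profile", "lfa_config_error")
  if (w > 1)
    values <- as.numeric(stats::runmed(values, w, endrule = "median"))
  structure(list(values = values,
                 pixels_per_mm = image$pixels_per_mm,
                 median_window_px = as.integer(w)),
            class = "intensity_profile")
}

# Local minima of a profile with topographic prominence (computed on the
# inverted signal). Plateaus contribute one candidate at their midpoint.
local_minima_prominence <- function(values) {
  u <- -values
  n <- length(u)
  # plateau-aware local maxima of u
  runs <- rle(u)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  peaks <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || runs$values[i - 1] < runs$values[i]
    right_ok <- i == k || runs$values[i + 1] < runs$values[i]
    if (i > 1L && i < k && left_ok && right_ok)
      peaks <- c(peaks, as.integer(floor((starts[i] + ends[i]) / 2)))
  }
  if (!length(peaks))
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    h <- u[p]
    # walk left to the next strictly higher point (or the edge)
    left_col <- h
    j <- p - 1L
    minv <- h
    while (j >= 1L && u[j] <= h) { minv <- min(minv, u[j]); j <- j - 1L }
    left_col <- minv
    right_col <- h
    j <- p + 1L
    minv <- h
    while (j <= n && u[j] <= h) { minv <- min(minv, u[j]); j <- j + 1L }
    right_col <- minv
    h - max(left_col, right_col)
  }, numeric(1))
  data.frame(index = peaks, value = values[peaks], prominence = prom)
}

line_peak <- function(position_px, raw_min, baseline, prominence) {
  structure(list(position_px = position_px,
                 raw_min = raw_min,
                 baseline = baseline,
                 depth = max(0, baseline - raw_min),
                 prominence = prominence),
            class = "line_peak")
}

profile_baseline <- function(values, centers_px, half_window_px) {
  idx0 <- seq_along(values) - 1L
  keep <- rep(TRUE, length(values))
  for (c0 in centers_px)
    keep <- keep & abs(idx0 - c0) > half_window_px
  if (!any(keep)) return(stats::median(values))
  stats::median(values[keep])
}

#' Detect test and control lines on an intensity profile
#'
#' Local minima are ranked by topographic prominence (of the inverted
#' profile). The two most prominent minima whose separation lies within
#' +/- 25% of `expected_separation_px` are retained; the upstream (lower
#' index) one is the test line and the downstream one the control line.
#' The baseline for depth measurement is the median of the profile outside
#' both line windows (centre +/- 1.5 line widths).
#'
#' When only one qualifying minimum exists it is accepted as the control
#' line provided both companion windows fit inside the profile; the test
#' line is then measured at `control - expected_separation_px` (a near-zero
#' depth, flagged `weak_test`, as produced by a sample saturating the
#' competitive response). If the downstream window runs off the profile the
#' control line cannot be confirmed and a missing-control error is raised.
#'
#' @param profile An `intensity_profile`.
#' @param expected_separation_px Expected centre-to-centre line separation
#'   in pixels.
#' @param min_prominence Minimum prominence (intensity units) for a minimum
#'   to count as a line (default 0.02).
#' @param line_width_px Line width in pixels, used for the baseline
#'   exclusion window; defaults to `expected_separation_px / 4` (a 1 mm
#'   line at 4 mm separation).
#' @return List with elements `test` and `control` (each a `line_peak`:
#'   0-based `position_px`, `raw_min`, `baseline`, `depth`, `prominence`)
#'   and `qc_flags` (character vector; `"extra_peaks"`, `"weak_test"`).
#' @export
detect_lines <- function(profile, expected_separation_px,
                         min_prominence = 0.02,
                         line_width_px = expected_separation_px / 4) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$values
  n <- length(v)
  if (n <= expected_separation_px)
    lfa_error("profile shorter than the expected line separation",
              "lfa_geometry_error")
  cand <- local_minima_prominence(v)
  cand <- cand[cand$prominence >= min_prominence, , drop = FALSE]
  cand <- cand[order(-cand$prominence), , drop = FALSE]
  qc <- character(0)
  sep_lo <- 0.75 * expected_separation_px
  sep_hi <- 1.25 * expected_separation_px
  half_win <- 1.5 * line_width_px

  if (nrow(cand) == 0)
    lfa_error("no line minima found: neither test nor control region shows a peak",
              c("lfa_missing_control_error", "lfa_missing_line_error"))

  if (nrow(cand) >= 2) {
    best <- NULL
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in (i + 1):nrow(cand)) {
        sep <- abs(cand$index[i] - cand$index[j])
        if (sep >= sep_lo && sep <= sep_hi) {
          best <- c(i, j)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) {
      if (nrow(cand) > 2) qc <- c(qc, "extra_peaks")
      pair <- cand[best, ]
      pair <- pair[order(pair$index), ]
      centers0 <- pair$index - 1L
      baseline <- profile_baseline(v, centers0, half_win)
      test <- line_peak(centers0[1], pair$value[1], baseline,
                        pair$prominence[1])
      control <- line_peak(centers0[2], pair$value[2], baseline,
                           pair$prominence[2])
      return(list(test = test, control = control, qc_flags = qc))
    }
    # fall through: several minima but no pair at the expected separation;
    # treat the most prominent as a lone candidate
  }

  # Lone candidate at 1-based index p. If the peak were the test line its
  # control companion would sit at p + separation; when that window runs off
  # the profile the control may simply have been cropped out, so refuse.
  # When the window is inside and empty, the peak must itself be the
  # control, with the test line saturated away (competitive format, high
  # analyte): measure the near-zero test depth upstream.
  p <- cand$index[1]
  down_end <- (p - 1) + sep_hi             # 0-based end of control window
  up_start <- (p - 1) - sep_hi
  if (down_end > n - 1) {
    lfa_error("control line region lies outside the cropped profile",
              c("lfa_missing_control_error", "lfa_missing_line_error"))
  }
  if (up_start < 0)
    lfa_error("test line region lies outside the cropped profile",
              c("lfa_missing_test_error", "lfa_missing_line_error"))
  # lone peak is the control; measure the (near-absent) test line upstream
  t_center <- (p - 1) - expected_separation_px
  t_lo <- max(1L, floor(t_center - line_width_px) + 1L)
  t_hi <- min(n, ceiling(t_center + line_width_px) + 1L)
  window <- v[t_lo:t_hi]
  t_idx <- t_lo + which.min(window) - 1L
  centers0 <- c(t_idx - 1L, p - 1L)
  baseline <- profile_baseline(v, centers0, half_win)
  qc <- c(qc, "weak_test")
  list(test = line_peak(t_idx - 1L, v[t_idx], baseline, 0),
       control = line_peak(p - 1L, cand$value[1], baseline,
                           cand$prominence[1]),
       qc_flags = qc)
}

#' Compute the T/C ratio from detected line peaks
#'
#' The ratio of baseline-relative depths, `test$depth / control$depth`.
#' Depths, not raw pixel minima, are used: the assay's zero-dose responses
#' (T/C near 4 in buffer, near 5.7 in serum) are only attainable as depth
#' ratios, and depths are invariant to illumination offsets.
#'
#' @param test,control `line_peak` objects from [detect_lines()].
#' @param qc_flags Flags carried over from detection.
#' @param min_control_depth Controls shallower than this (intensity units)
#'   indicate a failed strip and raise an invalid-test error (default
#'   0.02).
#' @return A `tc_result`: list with `test`, `control`, `tc_ratio`,
#'   `qc_flags`.
#' @export
compute_tc <- function(test, control, qc_flags = character(0),
                       min_control_depth = 0.02) {
  stopifnot(inherits(test, "line_peak"), inherits(control, "line_peak"))
  if (control$depth <= min_control_depth)
    lfa_error(sprintf(
      "control line depth %.4f at or below the minimum %.4f: failed strip",
      control$depth, min_control_depth), "lfa_invalid_test_error")
  structure(list(test = test, control = control,
                 tc_ratio = test$depth / control$depth,
                 qc_flags = qc_flags),
            class = "tc_result")
}

#' @export
print.tc_result <- function(x, ...) {
  cat(sprintf(
    "T/C = %.4f (test depth %.4f @ px %g, control depth %.4f @ px %g)%s\n",
    x$tc_ratio, x$test$depth, x$test$position_px,
    x$control$depth, x$control$position_px,
    if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","),
                                   "]") else ""))
  invisible(x)
}

stage_call <- function(stage, expr) {
  withCallingHandlers(expr, lfa_error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = unique(c(class(e), "lfa_stage_error"))))
  })
}

#' Quantify a strip image end to end
#'
#' Deterministic composition crop -> grayscale -> Gaussian denoise ->
#' median collapse -> line detection -> T/C computation, with every
#' parameter recorded in the result for provenance. Errors from a stage are
#' re-raised tagged with the stage name.
#'
#' @param image A `strip_image`, or a raw matrix / 3-channel array.
#' @param config A configuration list as produced by [default_config()];
#'   fields used: `roi`, `gaussian_sigma_px`, `median_window_px`,
#'   `expected_separation_px` (derived from `pixels_per_mm` and the default
#'   4 mm separation when `NULL`), `min_prominence`, `min_control_depth`,
#'   `line_width_px`.
#' @return A `tc_result` with a `provenance` element (parameters and config
#'   hash).
#' @export
quantify_image <- function(image, config = default_config()) {
  config <- validate_config(config)
  img <- stage_call("grayscale", to_grayscale(image))
  if (!is.null(config$roi))
    img <- stage_call("crop", crop_roi(img, config$roi))
  sep <- config$expected_separation_px
  if (is.null(sep)) {
    if (is.null(img$pixels_per_mm))
      lfa_error(paste0("expected_separation_px not set and the image has ",
                       "no pixels_per_mm scale"), "lfa_config_error")
    sep <- 4 * img$pixels_per_mm
  }
  lw <- if (is.null(config$line_width_px)) sep / 4 else config$line_width_px
  img <- stage_call("denoise", denoise(img, config$gaussian_sigma_px))
  prof <- stage_call("collapse",
                     collapse_to_profile(img, config$median_window_px))
  det <- stage_call("detect",
                    detect_lines(prof, expected_separation_px = sep,
                                 min_prominence = config$min_prominence,
                                 line_width_px = lw))
  res <- stage_call("ratio",
                    compute_tc(det$test, det$control, det$qc_flags,
                               min_control_depth = config$min_control_depth))
  res$provenance <- list(
    roi = config$roi,
    gaussian_sigma_px = config$gaussian_sigma_px,
    median_window_px = config$median_window_px,
    expected_separation_px = sep,
    line_width_px = lw,
    min_prominence = config$min_prominence,
    min_control_depth = config$min_control_depth,
    config_hash = config_hash(config))
  res
}
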