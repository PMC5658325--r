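#' Strip geometry for the simulated cassette window
#'
#' Physical layout of the imaged membrane: a nitrocellulose strip with two
#' dispensed reagent lines, the test line upstream (nearer the conjugate
#' pad) and the control line downstream. Defaults follow the assay build:
#' a 25 mm membrane with 1 mm lines separated by a 3 mm gap.
#'
#' @param membrane_length_mm Length of the imaged membrane (default 25).
#' @param line_width_mm Width of each dispensed line (default 1).
#' @param line_gap_mm Stated separation between the lines (default 3).
#' @param gap_is_edge_to_edge How to read `line_gap_mm`: `TRUE` (default)
#'   treats it as the clear gap between line edges, giving a
#'   centre-to-centre separation of `line_gap_mm + line_width_mm`; `FALSE`
#'   treats it as centre-to-centre directly. Exposed because dispensing
#'   protocols quote either convention.
#' @param test_line_position_mm Centre of the test line from the upstream
#'   edge of the membrane (default 10).
#' @param pixels_per_mm Raster resolution of the simulated camera
#'   (default 20, i.e. 50 um pixels).
#' @param strip_width_px Number of pixel rows across the strip (default 60).
#' @return A `strip_geometry` object; `$separation_mm` and
#'   `$control_line_position_mm` hold the derived layout.
#' @export
strip_geometry <- function(membrane_length_mm = 25,
                           line_width_mm = 1,
                           line_gap_mm = 3,
                           gap_is_edge_to_edge = TRUE,
                           test_line_position_mm = 10,
                           pixels_per_mm = 20,
                           strip_width_px = 60) {
  num <- c(membrane_length_mm, line_width_mm, line_gap_mm,
           test_line_position_mm, pixels_per_mm, strip_width_px)
  if (any(!is.finite(num)) || any(num <= 0))
    lfa_error("all geometry lengths must be positive finite numbers",
              "lfa_geometry_error")
  separation_mm <- if (isTRUE(gap_is_edge_to_edge))
    line_gap_mm + line_width_mm else line_gap_mm
  control_mm <- test_line_position_mm + separation_mm
  half <- line_width_mm / 2
  if (test_line_position_mm - half < 0 ||
      control_mm + half > membrane_length_mm)
    lfa_error("line positions (with half widths) must lie inside the membrane",
              "lfa_geometry_error")
  if (separation_mm <= line_width_mm)
    lfa_error("lines overlap: separation must exceed the line width",
              "lfa_geometry_error")
  structure(list(membrane_length_mm = membrane_length_mm,
                 line_width_mm = line_width_mm,
                 line_gap_mm = line_gap_mm,
                 gap_is_edge_to_edge = isTRUE(gap_is_edge_to_edge),
                 separation_mm = separation_mm,
                 test_line_position_mm = test_line_position_mm,
                 control_line_position_mm = control_mm,
                 pixels_per_mm = pixels_per_mm,
                 strip_width_px = as.integer(strip_width_px)),
            class = "strip_geometry")
}

#' Optical model of a simulated strip image
#'
#' Signal model on a 0-1 intensity scale: a light membrane at
#' `background_intensity`, two dark Gaussian-edged bands of depth
#' `control_depth * tc_ratio_true` (test) and `control_depth` (control),
#' an optional linear illumination gradient along the flow axis, and i.i.d.
#' additive Gaussian pixel noise. The polarity encodes the competitive
#' format: a deficient (low-analyte) sample has a deep test line and a high
#' T/C ratio.
#'
#' @param background_intensity Mean blank-membrane intensity in (0, 1].
#' @param control_depth Maximal darkening of the control line, intensity
#'   units (> 0).
#' @param tc_ratio_true Ground-truth ratio of test-line depth to
#'   control-line depth (>= 0).
#' @param line_profile_sigma_mm Gaussian smoothing of the line edges in mm
#'   (the dispensed rectangle convolved with this kernel).
#' @param noise_sigma Additive pixel-noise standard deviation.
#' @param illumination_slope Linear intensity gradient along the flow axis
#'   (intensity units per mm, centred on the membrane midpoint); default 0.
#' @param seed Optional RNG seed making the rendered noise reproducible.
#' @return An `optical_model` object.
#' @export
optical_model <- function(background_intensity = 0.85,
                          control_depth = 0.12,
                          tc_ratio_true = 1,
                          line_profile_sigma_mm = 0.15,
                          noise_sigma = 0,
                          illumination_slope = 0,
                          seed = NULL) {
  if (!is_scalar_number(background_intensity) ||
      background_intensity <= 0 || background_intensity > 1)
    lfa_error("background_intensity must lie in (0, 1]", "lfa_model_error")
  if (!is_scalar_number(control_depth) || control_depth <= 0)
    lfa_error("control_depth must be > 0", "lfa_model_error")
  if (!is_scalar_number(tc_ratio_true) || tc_ratio_true < 0)
    lfa_error("tc_ratio_true must be >= 0", "lfa_model_error")
  if (!is_scalar_number(line_profile_sigma_mm) || line_profile_sigma_mm < 0)
    lfa_error("line_profile_sigma_mm must be >= 0", "lfa_model_error")
  if (!is_scalar_number(noise_sigma) || noise_sigma < 0)
    lfa_error("noise_sigma must be >= 0", "lfa_model_error")
  if (!is_scalar_number(illumination_slope))
    lfa_error("illumination_slope must be a finite number", "lfa_model_error")
  structure(list(background_intensity = background_intensity,
                 control_depth = control_depth,
                 tc_ratio_true = tc_ratio_true,
                 line_profile_sigma_mm = line_profile_sigma_mm,
                 noise_sigma = noise_sigma,
                 illumination_slope = illumination_slope,
                 seed = seed),
            class = "optical_model")
}

# Unit-height cross-section of a dispensed line: rectangle of width w_mm
# centred at c_mm, convolved with a Gaussian of sd sigma_mm.
line_band <- function(x_mm, center_mm, width_mm, sigma_mm) {
  half <- width_mm / 2
  if (sigma_mm == 0)
    return(as.numeric(abs(x_mm - center_mm) <= half))
  stats::pnorm((x_mm - (center_mm - half)) / sigma_mm) -
    stats::pnorm((x_mm - (center_mm + half)) / sigma_mm)
}

#' Render a synthetic strip image with known ground truth
#'
#' Produces a grayscale raster of the cassette window (rows across the
#' strip, columns along the flow axis) from a [strip_geometry()] and an
#' [optical_model()], with the generating truth attached as a manifest.
#' Parameter combinations whose line troughs would clip at 0 are refused:
#' a saturated simulation has no recoverable T/C.
#'
#' @param geom A `strip_geometry`.
#' @param optics An `optical_model`.
#' @param concentration_nmol_L Optional true concentration recorded in the
#'   manifest (purely metadata; the rendered T/C is `optics$tc_ratio_true`).
#' @return A `strip_image`: list with `pixels` (matrix in \[0, 1\]),
#'   `pixels_per_mm`, `roi` (NULL until cropped) and `truth` (ground-truth
#'   manifest: `tc_ratio_true`, line centre pixel indices (0-based),
#'   depths, seed and a geometry hash).
#' @export
render_strip <- function(geom, optics, concentration_nmol_L = NA_real_) {
  stopifnot(inherits(geom, "strip_geometry"),
            inherits(optics, "optical_model"))
  test_depth <- optics$control_depth * optics$tc_ratio_true
  span <- abs(optics$illumination_slope) * geom$membrane_length_mm / 2
  floor_val <- optics$background_intensity - span -
    max(test_depth, optics$control_depth)
  if (floor_val < 0)
    lfa_error(sprintf(
      paste0("line troughs would clip at 0 (minimum attainable intensity ",
             "%.3f); reduce control_depth, tc_ratio_true or the ",
             "illumination slope"), floor_val),
      "lfa_model_error")
  n_col <- round(geom$membrane_length_mm * geom$pixels_per_mm)
  x_mm <- (seq_len(n_col) - 0.5) / geom$pixels_per_mm
  base <- optics$background_intensity +
    optics$illumination_slope * (x_mm - geom$membrane_length_mm / 2)
  profile <- base -
    test_depth * line_band(x_mm, geom$test_line_position_mm,
                           geom$line_width_mm, optics$line_profile_sigma_mm) -
    optics$control_depth * line_band(x_mm, geom$control_line_position_mm,
                                     geom$line_width_mm,
                                     optics$line_profile_sigma_mm)
  n_row <- geom$strip_width_px
  pixels <- matrix(profile, nrow = n_row, ncol = n_col, byrow = TRUE)
  if (optics$noise_sigma > 0) {
    noise <- with_optional_seed(optics$seed,
      matrix(stats::rnorm(n_row * n_col, 0, optics$noise_sigma),
             nrow = n_row))
    pixels <- pixels + noise
  }
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  truth <- list(concentration_nmol_L = concentration_nmol_L,
                tc_ratio_true = optics$tc_ratio_true,
                test_center_px = geom$test_line_position_mm *
                  geom$pixels_per_mm - 0.5,
                control_center_px = geom$control_line_position_mm *
                  geom$pixels_per_mm - 0.5,
                test_depth = test_depth,
                control_depth = optics$control_depth,
                noise_sigma = optics$noise_sigma,
                seed = optics$seed,
                geometry_hash = config_hash(unclass(geom)))
  strip_image(pixels, pixels_per_mm = geom$pixels_per_mm, truth = truth)
}

#' Forward assay response
#'
#' Alias of [predict_tc()] with arguments in simulator order: the T/C ratio
#' the assay produces at a given true concentration under a calibration
#' model.
#'
#' @inheritParams predict_tc
#' @export
concentration_to_tc <- function(conc, model) {
  predict_tc(model, conc)
}

resolve_sampler <- function(conc_sampler, n) {
  if (is.function(conc_sampler)) return(conc_sampler(n))
  if (is.numeric(conc_sampler)) {
    if (length(conc_sampler) == n) return(conc_sampler)
    if (length(conc_sampler) == 1) return(rep(conc_sampler, n))
    lfa_error("numeric conc_sampler must have length 1 or n",
              "lfa_config_error")
  }
  if (is.list(conc_sampler) && !is.null(conc_sampler$dist)) {
    return(switch(conc_sampler$dist,
      uniform = stats::runif(n, conc_sampler$min, conc_sampler$max),
      normal = pmax(0, stats::rnorm(n, conc_sampler$mean, conc_sampler$sd)),
      lognormal = stats::rlnorm(n, conc_sampler$meanlog, conc_sampler$sdlog),
      lfa_error(sprintf("unsupported sampler distribution '%s'",
                        conc_sampler$dist), "lfa_config_error")))
  }
  lfa_error("conc_sampler must be a function, numeric vector, or dist spec",
            "lfa_config_error")
}

#' Simulate a cohort of subjects with known ground truth
#'
#' Draws true concentrations from a sampler, pushes them through the forward
#' calibration model, perturbs the resulting T/C ratios multiplicatively to
#' emulate replicate strip variability, and labels each subject under the
#' Endocrine Society thresholds. Optionally renders a strip image per
#' subject.
#'
#' @param n Number of subjects (>= 1).
#' @param model Forward `calibration_model`.
#' @param conc_sampler One of: a function of `n` returning concentrations; a
#'   numeric vector (length `n` or 1) of fixed concentrations; or a list
#'   spec like `list(dist = "uniform", min = 0, max = 150)` (`"normal"`
#'   with `mean`/`sd`, truncated at 0, and `"lognormal"` with
#'   `meanlog`/`sdlog` are also accepted).
#' @param replicate_cv Fractional coefficient of variation of the
#'   multiplicative T/C perturbation (0 = points exactly on the curve).
#' @param seed RNG seed; the same seed reproduces the cohort bit-for-bit.
#' @param render If `TRUE`, a noiseless-by-default strip is rendered per
#'   subject at its perturbed T/C (attached as attribute `"strips"`).
#' @param geometry,optics Templates used when `render = TRUE`; the per
#'   subject `tc_ratio_true` overrides the template value.
#' @return Data frame with columns `id`, `conc`, `tc_true` (on-curve),
#'   `tc` (perturbed) and `label`.
#' @export
simulate_cohort <- function(n, model,
                            conc_sampler = list(dist = "uniform",
                                                min = 0, max = 150),
                            replicate_cv = 0, seed = NULL,
                            render = FALSE,
                            geometry = strip_geometry(),
                            optics = optical_model()) {
  if (!is_scalar_number(n) || n < 1)
    lfa_error("n must be >= 1", "lfa_input_error")
  if (!is_scalar_number(replicate_cv) || replicate_cv < 0)
    lfa_error("replicate_cv must be >= 0", "lfa_input_error")
  n <- as.integer(n)
  cohort <- with_optional_seed(seed, {
    conc <- resolve_sampler(conc_sampler, n)
    check_conc_domain(conc)
    tc_true <- predict_tc(model, conc)
    factor_noise <- if (replicate_cv > 0)
      stats::rnorm(n, mean = 1, sd = replicate_cv) else rep(1, n)
    tc <- pmax(0, tc_true * factor_noise)
    data.frame(id = sprintf("s%04d", seq_len(n)),
               conc = conc, tc_true = tc_true, tc = tc,
               label = classify_status(conc))
  })
  if (isTRUE(render)) {
    strips <- lapply(seq_len(n), function(i) {
      op <- optics
      op$tc_ratio_true <- cohort$tc[i]
      op$seed <- if (is.null(seed)) NULL else seed + i
      render_strip(geometry, op,
                   concentration_nmol_L = cohort$conc[i])
    })
    attr(cohort, "strips") <- strips
  }
  cohort
}

#' Write a simulated batch to disk
#'
#' Saves each rendered strip as an image plus a CSV ground-truth manifest
#' (one row per strip: id, concentration, true T/C, seed, geometry hash).
#'
#' @param cohort Output of [simulate_cohort()] with `render = TRUE`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return Invisibly, the manifest data frame.
#' @export
write_simulated_batch <- function(cohort, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  strips <- attr(cohort, "strips")
  if (is.null(strips))
    lfa_error("cohort has no rendered strips (use render = TRUE)",
              "lfa_input_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(seq_along(strips), function(i) {
    s <- strips[[i]]
    file <- file.path(dir, paste0(cohort$id[i], ".", format))
    write_strip_image(s, file)
    data.frame(id = cohort$id[i], file = basename(file),
               concentration_nmol_L = s$truth$concentration_nmol_L,
               tc_ratio_true = s$truth$tc_ratio_true,
               seed = if (is.null(s$truth$seed)) NA_integer_ else s$truth$seed,
               geometry_hash = s$truth$geometry_hash)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
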