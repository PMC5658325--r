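#' Guideline threshold sets for vitamin-D status
#'
#' A threshold set names two bounds on serum 25(OH)D3 (nmol/L):
#' concentrations strictly below `deficient_below` are deficient, values
#' from `deficient_below` to `sufficient_above` inclusive are insufficient,
#' and values strictly above `sufficient_above` are sufficient. The default
#' preset is the Endocrine Society guideline (50 / 75 nmol/L); `"iom_50"`
#' and `"iom_30"` are the Institute of Medicine style single cutoffs used
#' for dichotomous (ROC) analysis, expressed as degenerate sets with both
#' bounds equal. Presets are stored in a JSON registry shipped with the
#' package (`inst/extdata/thresholds.json`).
#'
#' @param name Preset name, or `NULL` to list all presets.
#' @return A `threshold_set` (or a named list of them when `name = NULL`).
#' @export
vitd_thresholds <- function(name = "endocrine_society") {
  path <- system.file("extdata", "thresholds.json", package = "lfaquant")
  registry <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(nm) {
    e <- registry[[nm]]
    threshold_set(nm, e$deficient_below, e$sufficient_above)
  }
  if (is.null(name))
    return(stats::setNames(lapply(names(registry), build), names(registry)))
  if (!name %in% names(registry))
    lfa_error(sprintf("unknown threshold preset '%s' (have: %s)", name,
                      paste(names(registry), collapse = ", ")),
              "lfa_config_error")
  build(name)
}

#' @rdname vitd_thresholds
#' @param set_name Label of the guideline.
#' @param deficient_below,sufficient_above Bounds in nmol/L with
#'   `0 < deficient_below <= sufficient_above`.
#' @export
threshold_set <- function(set_name, deficient_below, sufficient_above) {
  if (!is_scalar_number(deficient_below) ||
      !is_scalar_number(sufficient_above) ||
      deficient_below <= 0 || deficient_below > sufficient_above)
    lfa_error("need 0 < deficient_below <= sufficient_above",
              "lfa_config_error")
  structure(list(name = set_name,
                 deficient_below = deficient_below,
                 sufficient_above = sufficient_above),
            class = "threshold_set")
}

status_levels <- c("deficient", "insufficient", "sufficient",
                   "indeterminate")

#' Classify vitamin-D status from a concentration
#'
#' Step classification under a [threshold_set]. The boundary convention
#' follows the guideline wording literally: "lower than 50" is strict, so
#' exactly 50 and exactly 75 nmol/L are both insufficient ("between 50 and
#' 75" read inclusive).
#'
#' Censored results (from out-of-range calibration inversion) are handled
#' conservatively: a "below limit" value whose limit is under the deficient
#' bound is deficient; an "above limit" value whose limit exceeds the
#' sufficient bound is sufficient; anything else is indeterminate.
#'
#' @param conc Numeric vector of concentrations in nmol/L (for censored
#'   entries, the censoring limit).
#' @param thresholds A `threshold_set` (default Endocrine Society 50/75).
#' @param censor Optional factor/character parallel to `conc` with values
#'   `"none"`, `"below_range"`, `"above_range"` as returned by
#'   [invert_tc()].
#' @return Factor with levels deficient, insufficient, sufficient,
#'   indeterminate.
#' @export
classify_status <- function(conc, thresholds = vitd_thresholds(),
                            censor = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (is.null(censor)) censor <- rep("none", length(conc))
  censor <- as.character(censor)
  if (length(censor) != length(conc))
    lfa_error("censor must be parallel to conc", "lfa_input_error")
  plain <- censor == "none"
  if (any(plain & (!is.finite(conc) | conc < 0)))
    lfa_error("negative or non-finite uncensored concentration",
              "lfa_domain_error")
  lo <- thresholds$deficient_below
  hi <- thresholds$sufficient_above
  out <- rep("indeterminate", length(conc))
  out[plain & conc < lo] <- "deficient"
  out[plain & conc >= lo & conc <= hi] <- "insufficient"
  out[plain & conc > hi] <- "sufficient"
  below <- censor == "below_range"
  out[below & conc < lo] <- "deficient"
  above <- censor == "above_range"
  out[above & (!is.finite(conc) | conc > hi)] <- "sufficient"
  factor(out, levels = status_levels)
}

#' Dichotomize a concentration at a cutoff
#'
#' Used for ROC analysis at a single guideline cutoff. `below` iff
#' `conc < cutoff`; a value exactly at the cutoff is `at_or_above`.
#'
#' @param conc Numeric vector of concentrations in nmol/L.
#' @param cutoff Cutoff in nmol/L (e.g. 50 or 30).
#' @return Factor with levels `below`, `at_or_above`.
#' @export
binarize <- function(conc, cutoff) {
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    lfa_error("cutoff must be a positive number", "lfa_config_error")
  if (any(!is.finite(conc) | conc < 0))
    lfa_error("negative or non-finite concentration", "lfa_domain_error")
  factor(ifelse(conc < cutoff, "below", "at_or_above"),
         levels = c("below", "at_or_above"))
}
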