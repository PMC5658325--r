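# Shared fixtures and independent oracles, built in code at test time.

ref_cal <- vitd_reference_calibrations()

# Noiseless default-geometry strip at a given true T/C.
make_strip <- function(tc, ...) {
  render_strip(strip_geometry(),
               optical_model(tc_ratio_true = tc, ...))
}

# Independent AUC oracle: exhaustive pair counting with ties at 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Equal-variance binormal scores with a chosen generative AUC:
# AUC = Phi(delta / sqrt(2))  =>  delta = sqrt(2) * qnorm(AUC).
binormal_cohort <- function(n_pos, n_neg, auc) {
  delta <- sqrt(2) * qnorm(auc)
  list(scores = c(rnorm(n_pos, mean = delta), rnorm(n_neg)),
       labels = c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
}

# Concentration design of the serum-calibrator dose-response experiment:
# 16 levels spanning 0-150 nmol/L, denser below the inflection.
calibrator_design <- c(0, 5, 10, 15, 20, 25, 30, 40,
                       50, 60, 75, 90, 105, 120, 135, 150)
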