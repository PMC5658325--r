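# lfaquant

Quantification chain for competitive lateral-flow immunoassay strips read
by an imaging device, built around a point-of-need 25-hydroxyvitamin D3
(25(OH)D3) assay.

Point-of-need vitamin-D testing uses a competitive lateral-flow strip: the
analyte is too small to sandwich, so sample 25(OH)D3 competes with
immobilised 25(OH)D3-BSA for gold-conjugated antibody. The signal is
therefore inverted — a deficient subject shows a *dark* test line and a
*high* test/control (T/C) ratio. `lfaquant` turns a grayscale image of the
cassette window into that ratio, converts it to a concentration through a
calibration curve, assigns a vitamin-D status, and scores diagnostic
performance. A ground-truth strip simulator makes the whole chain testable
end to end.

The package is aimed at assay developers and diagnostics researchers who
need a reproducible, scriptable strip-reader backend rather than a
device-bound one.

## What it computes

**Densitometry.** An image is cropped to a registered ROI, converted to
luminance, Gaussian-smoothed, collapsed to a 1D profile (per-column median,
then a running median), and the test and control lines are found as the
two most prominent local minima at the expected separation. The T/C ratio
is the ratio of baseline-relative depths,

    T/C = (baseline − test minimum) / (baseline − control minimum),

with the baseline estimated as the median profile intensity outside both
line windows.

**Calibration.** Concentration `x` (nmol/L) maps to ratio `y` either
linearly, `y = a x + b` (ordinary least squares), or through a
four-parameter logistic,

    y = d + (a − d) / (1 + (x/c)^b),

fitted by Levenberg-Marquardt with documented initialisation and bounds
(`b, c > 0`). Both invert in closed form; out-of-range ratios are censored
("> upper limit" style), not errors.

**Classification.** Endocrine Society bands: deficient < 50 nmol/L,
insufficient 50-75 (inclusive), sufficient > 75; single-cutoff (50, 30
nmol/L) presets for dichotomous analysis.

**Evaluation.** Empirical ROC, DeLong AUC with structural-components
variance and 95% CI, stratified bootstrap AUC, diagnostic accuracy with
exact rationals, RMSE, and replicate coefficient of variation.

## Worked example

Simulate four noiseless strips at known concentrations through the
reported human-serum calibration (`T/C = −0.075·x + 5.689`), then run the
full pipeline back to concentrations and statuses:

```r
library(lfaquant)
cal <- vitd_reference_calibrations()$serum_linear
conc <- c(15, 35, 55, 70)
strips <- lapply(predict_tc(cal, conc), function(tc)
  render_strip(strip_geometry(), optical_model(tc_ratio_true = tc)))
report <- run_pipeline(strips, calibration = cal)
report$results[, c("id", "tc_ratio", "conc_nmol_L", "status")]
#>         id tc_ratio conc_nmol_L       status
#> 1 image001    4.564          15    deficient
#> 2 image002    3.064          35    deficient
#> 3 image003    1.564          55 insufficient
#> 4 image004    0.439          70 insufficient
```

The extracted ratios sit exactly on the forward curve (e.g. 15 nmol/L →
T/C 4.564) and the inverted concentrations recover the inputs to machine
precision — on noiseless renders the render→extract round trip is exact to
better than 1e-3 by design, and tested.

Refitting a 4PL to noiseless points from the reported serum-calibrator
curve recovers every printed parameter:

```r
design <- c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 75, 90, 105, 120, 135, 150)
fit_4pl(design, predict_tc(vitd_reference_calibrations()$calibrator_4pl, design))
#> 4PL calibration: T/C = 1.52 + (2.81 - 1.52)/(1 + ([25(OH)D3]/26.2)^2.63)
#>   n = 16, R^2 = 1.0000, RMSE(T/C) = 9.615e-17, converged = TRUE
```

A DeLong AUC on a 200-subject binormal cohort with generative AUC 0.836:

```r
set.seed(1)
delta <- sqrt(2) * qnorm(0.836)
scores <- c(rnorm(100, delta), rnorm(100))
auc_delong(scores, rep(c(TRUE, FALSE), each = 100))
#> AUC = 0.8718 (delong; 100 pos / 100 neg)
#>   95% CI [0.8226, 0.9210]
```

## Command line

A thin Rscript wrapper ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lfaquant.R", package = "lfaquant"))')
Rscript $CLI simulate  --n 10 --calibration cal.json --seed 3 --out strips/
Rscript $CLI quantify  strips/*.png --out results.csv
Rscript $CLI calibrate --model 4pl --in points.csv --out cal.json
Rscript $CLI predict   --calib cal.json --tc 2.5
Rscript $CLI evaluate  --cohort cohort.csv --cutoff 50 --out report.json
Rscript $CLI run       strips/*.png --calib cal.json --out results.csv
```

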