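---
title: "Chemometric classification of Raman spectra: preprocessing, DAPC and leave-one-out validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric classification of Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanclass)
```

## The problem

A Raman spectrum of a biological fluid is a molecular fingerprint: hundreds
of overlapping vibrational bands whose relative intensities track the
sample's broad composition. Chemometric screening asks a deliberately
modest question of such fingerprints — not *which* molecules differ, but
*whether* a spectrum belongs to one group or another (for instance, urine
from a healthy donor versus a patient with advanced chronic kidney
disease). `ramanclass` implements the standard pipeline for that question:
spectral preprocessing, principal component analysis (PCA), linear
discriminant classification in PC-score space (DAPC), and — crucially —
grouped leave-one-out (LOO) validation that tells you how well the model
predicts spectra it has never seen, compared against explicit
random-chance floors.

## Preprocessing model

Each scan passes through four steps, in a fixed order:

1. **Truncation** to the fingerprint window, 400–1800 cm⁻¹ by default.
   The interval is closed: grid points equal to either bound are kept.
2. **Baseline correction.** Fluorescence and scattering put a smooth,
   slowly varying background under the Raman bands. We model it as a
   polynomial of order ≤ 3 and estimate it by an iterative asymmetric
   scheme: starting from the ordinary least-squares fit, points whose
   residual exceeds the (1 − `peak_ratio`) quantile of the residuals
   (floored at zero) are excluded from the next weighted refit, while
   points at or below the fit always keep full weight. Peaks — which only
   ever add intensity — therefore stop pulling the fit upward, and on
   peak-free polynomial input the procedure reproduces the least-squares
   fit exactly. `peak_ratio` (default 0.5) is the assumed fraction of
   grid points carrying peak signal; a copy smoothed with the
   moving-average `smooth_window` (default 5) is used only when deciding
   which points count as peak signal — the polynomial is fitted to, and
   subtracted from, the raw intensities, so smoothing never touches the
   corrected output.
3. **Vector normalization** to unit Euclidean norm, removing overall
   intensity differences between scans (laser power, focus, integration).
4. **Replicate averaging**, pointwise, per specimen (or per individual).
   The class label must be unanimous within a group.

Because normalization precedes averaging, an averaged spectrum has norm
≤ 1 rather than exactly 1 (unit vectors average to a shorter vector unless
they are parallel). We keep that order — it matches how replicate scans
are conventionally processed — and provide a `renormalize_after_average`
flag (default off) for users who want unit-norm output.

### Numerical choices in the baseline fit

* Polynomial basis: orthogonal polynomials on the grid rescaled to
  [−1, 1], for conditioning; the fitted curve is identical to a raw-power
  fit of the same order.
* Convergence: the iteration stops when the baseline changes by less than
  `tol = 1e-6` (relative, sup-norm), or when the active point set repeats
  — either a fixed point or a deterministic limit cycle, which the
  discrete reweighting can enter on noisy input; in a cycle the competing
  baselines differ negligibly and the current one is returned. Exceeding
  `max_iter = 200` raises an error that reports the last relative change.
* Degenerate inputs: an all-zero spectrum yields the zero baseline; a
  window with fewer grid points than `poly_order + 1` is an error.

## PCA and DAPC

PCA is the mean-centered singular value decomposition of the scan × point
matrix; explained-variance fractions are singular values squared over
their total. Each loading's sign is fixed so its largest-magnitude entry
is positive, making fits reproducible bit-for-bit.

DAPC retains the first *k* PC scores and applies a *linear* discriminant:
pooled (equal) within-class covariance, per-class score means, and the
discriminant score

$$\delta_c(s) = s^\top W \mu_c - \tfrac12 \mu_c^\top W \mu_c + \log \pi_c,$$

where $W$ is the pseudo-inverse of the pooled within-class covariance and
$\pi_c$ the class prior. Priors are **uniform** by default (configurable
to proportional): chance for a two-class problem is then 50% regardless
of class imbalance, which is how screening results are conventionally
judged. Ties break to the alphabetically first class.

Two deliberate choices deserve emphasis:

* **Pseudo-inverse, no shrinkage.** As *k* approaches the number of
  training spectra the pooled covariance becomes ill-conditioned and
  finally singular. We invert it with an eigenvalue tolerance
  (dimension × machine epsilon × largest eigenvalue) rather than
  regularizing, precisely so that over-fitting *shows up* in validation
  instead of being quietly suppressed. A subtle consequence: at exactly
  singular *k* the pseudo-inverse discards the null directions and
  accuracy partially recovers; the worst behavior sits just *below* the
  rank, where tiny-but-nonzero eigenvalues amplify noise. Validation
  sweeps should therefore probe k near, not only at, the rank bound.
* **Linear, not quadratic.** DAPC conventionally uses a common covariance;
  with uniform priors the rule coincides with Mahalanobis
  nearest-centroid classification up to shared terms.

Canonical coordinates for cluster plots are eigenvectors of $W B$ ($B$ the
between-class scatter of class means); with two classes there is one
non-trivial axis and the second plotted coordinate is zero.

## Leave-one-out validation and chance floors

The validation unit is the **specimen** by default (each specimen's
averaged spectrum is held out and predicted by a model refit on the
rest), with an individual-level option that holds out all specimens of a
person at once — the appropriate unit when individuals contribute
multiple specimens and the clinical question is about the person.
Everything is refit per fold: centering, loadings, class means,
covariance. Accuracy is the percentage of correctly classified spectra;
sensitivity and specificity are computed against a user-designated
positive class (disease = positive in the screening use case). Undefined
ratios (an empty class) are reported as `NA` with a warning, never
coerced to 0 or 100. `pc_sweep()` repeats this over a grid of *k* and
tabulates the metrics next to the cumulative variance explained by a
full-data PCA (one value per *k*; the per-fold PCAs differ only
marginally and a single column is what sweep tables conventionally show).

Two chance models calibrate the results:

* `uniform-guess` — closed form for a classifier guessing uniformly over
  the g classes: accuracy = sensitivity = 100/g, specificity =
  100 (g−1)/g, independent of class representation (50/50/50 for any
  two-class dataset).
* `permutation` — predicted labels are a random permutation of the true
  labels, preserving class proportions; Monte-Carlo means ± standard
  errors, expected accuracy $\sum_c p_c^2$.

## The synthetic generator

`generate_dataset()` emulates liquid-sample Raman data well enough to
exercise every pipeline stage against known ground truth: per specimen, a
random cubic baseline (uniform coefficients on a rescaled axis) plus five
Gaussian fingerprint bands (including a strong band at ~1003 cm⁻¹, where
urea dominates urine spectra) with per-specimen amplitude factors
(SD `specimen_sd` = 0.05); per replicate scan, iid Gaussian noise
(`noise_sd` = 0.02); 10 replicates per specimen, mirroring common
acquisition practice. Defaults use a 400–1800 cm⁻¹ grid at 1 cm⁻¹.

Two design points matter for interpreting tests built on it:

* **Class effects act on marker bands.** A multiplicative factor applied
  uniformly to *every* band is cancelled exactly by vector normalization
  — the normalized spectral shape is unchanged — so such a "class effect"
  is invisible to the pipeline by construction. The generator therefore
  applies the per-class factor (default 1.25 on the "unhealthy" class) to
  a subset of marker bands (`effect_peaks`, default bands 2 and 4),
  changing relative band intensities the way a real compositional
  difference does. A full class × band matrix can be supplied instead.
* **Specimen-level clutter.** Each specimen also receives 30 minor bands
  at random positions, widths 8–40 cm⁻¹ and amplitudes up to 0.05,
  emulating the low-abundance compounds whose levels vary from person to
  person. Without clutter the within-class spectra live on a ~5-dim
  manifold and high-k discriminant models barely over-fit; with it, the
  within-class covariance is genuinely high-dimensional and the
  characteristic accuracy decline at large k emerges, as it does in real
  datasets.

What the generator does **not** model: Raman peak-shape physics
(Lorentzian tails are an option, not a calibration), instrument response,
cosmic-ray spikes, wavenumber miscalibration, or any real urine
chemistry. Passing tests demonstrate that the pipeline recovers known
structure under realistic noise geometry — not clinical performance.

## Study sizes used by the automated checks

The package's end-to-end checks run at desk scale, chosen to finish in
minutes while leaving the phenomena visible: separability recovery uses
8 + 8 specimens at class effect 2 and noise 0.005 (marker-band intensity
doubled — large relative to the specimen variability and clutter, so
recovery is expected regardless of the random draw);
the over-fitting check uses 20 + 30 specimens at class effect 1.10,
comparing mean LOO accuracy over 10 seeds at k = 10 versus k = 46 (the
training fold of 49 spectra has rank 48); null calibration uses 20 + 20
specimens with no class effect over 20 seeds, compared against the
permutation-chance accuracy within three combined standard errors (LOO
cross-validation is known to run slightly pessimistic at these sample
sizes, and does so here, within the band). Baseline recovery demands
≤ 2% of peak height off-peak on random cubics with two sparse peaks, and
exact (≤ 1e-6 relative) agreement with the least-squares fit on
peak-free polynomials.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_specimens_per_class = 8, class_effects = c(1, 2),
                    noise_sd = 0.005, seed = 42)
gen <- generate_dataset(cfg)
proc <- run_preprocess(gen$dataset, preprocess_config())
report <- pc_sweep(proc$dataset, c(2, 5, 10), positive_class = "unhealthy")
print(report)
random_chance(proc$dataset$meta$class_label)
```

## Known limitations

* The baseline model is a single polynomial per spectrum; structured
  backgrounds (étaloning, sharp fluorescence edges) need different tools.
* No shrinkage/regularized discriminants: by design, large-k models are
  allowed to fail loudly in validation rather than be rescued.
* The permutation chance model shuffles labels as a whole; it does not
  condition on a particular classifier's confusion structure.
* Interchange is delimited text only; vendor binary formats must be
  converted upstream.
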