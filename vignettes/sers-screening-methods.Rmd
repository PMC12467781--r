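---
title: "Serum SERS screening: models, preprocessing and the PLS-SVM classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum SERS screening: models, preprocessing and the PLS-SVM classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersdx)
```

# The problem

Surface-enhanced Raman scattering (SERS) of serum is a candidate screening
tool for postmenopausal osteoporosis: the disease shifts the concentrations of
circulating metabolites (amino acids, lipids, collagen fragments), and those
shifts appear as small intensity changes of assigned Raman bands. In the rat
model the three study arms are sham-operated controls (`Sham`), the
ovariectomized disease model (`OVX`), and ovariectomized animals treated with
icariin (`ICA`). The analysis chain is:

1. acquire replicate SERS spectra per serum sample and average them,
2. strip the broad autofluorescence background and area-normalize,
3. compare band intensities between groups with assumption-routed tests,
4. classify samples with PLS latent components fed into an RBF-kernel SVM
   under stratified 10-fold cross-validation.

The original serum data are not publicly deposited, so this package ships a
seeded synthetic-cohort generator that reproduces the study's *design* (3
groups x 30 samples x 10 replicates, 400--1800 cm^-1 at 2 cm^-1, the 14
assigned bands, the published direction of each group effect) and uses it to
test every stage.

# The synthetic-data model

Each raw spectrum is

$$ y(\nu) \;=\; b(\nu) \;+\; f_s\, f_r \sum_{j=1}^{14} m_{g,j}\, A_j
   \frac{w_j^2}{(\nu - c_j)^2 + w_j^2} \;+\; \varepsilon(\nu), $$

with a Lorentzian line shape per band (amplitude $A_j$ at center $c_j$,
half-width at half-maximum $w_j = 6$ cm^-1 -- the conventional shape for
Raman bands), a group multiplier $m_{g,j}$, a log-normal between-sample
factor $f_s$ (shared by all replicates of a sample) and between-replicate
factor $f_r$, i.i.d. Gaussian noise $\varepsilon$, and a degree-4 polynomial
background $b(\nu)$ evaluated on the scaled coordinate
$u = (\nu - 1100)/700 \in [-1, 1]$.

Parameter defaults and why:

* **Band template.** The 14 positions are the assigned serum bands (490,
  524, 588, 635, 802, 883, 1004, 1064, 1127, 1197, 1323, 1379, 1575,
  1647 cm^-1). Amplitudes (30--100 counts) are a generator choice sized so
  the phenylalanine ring-breathing band at 1004 cm^-1 dominates, as it does
  in serum spectra; the source study does not publish intensities.
* **Group effects.** `OVX` multiplies the 635 cm^-1 tyrosine band by 1.35
  and the six depressed bands (490, 1064, 1197, 1323, 1379, 1647 cm^-1) by
  0.72; `ICA` sits 45% of the way from `Sham` to `OVX` on each affected
  band, encoding the published finding that treatment partially -- not fully
  -- restores the serum biochemistry. Effect sizes of 25--35% were chosen
  once as plausible for metabolite-level changes; only the directions are
  published.
* **Background.** Coefficients (200, 80, -50, -30, 20) on $1, u, \dots,
  u^4$: positive everywhere (120--226 counts), smooth, and larger than any
  single band -- the regime in which fluorescence removal matters.
* **Noise scales.** `noise_sd = 2` counts per grid point (a few percent of
  the strong bands), `sample_sd = 0.08` and `replicate_sd = 0.05` (log-SDs
  of the multiplicative factors). The study reports none of these; they are
  documented tunables, not the study's values, and the acceptance checks
  treat them as the fixed simulation conditions.
* **Seeding.** One root seed; every spectrum draws from a sub-stream keyed
  by (group, sample, replicate), so any subset of the cohort regenerates
  bit-identically and the sample factor is shared across a sample's
  replicates.

What the generator does *not* emulate: wavenumber calibration drift, cosmic
ray spikes, detector saturation, heteroscedastic shot noise, and peak-shape
asymmetry. Passing tests therefore demonstrate correctness of the analysis
chain under the stated model, not robustness to every artifact of real
acquisitions.

# Fluorescence-baseline removal

`remove_baseline()` implements iterative modified multi-polynomial fitting
(the Vancouver Raman Algorithm family): fit a polynomial (default order 5) to
the working signal, estimate the residual noise scale, replace every point
above `fit + strip_factor * noise` by the fit (peak stripping), and repeat.
Two implementation choices deserve notice:

* **Noise estimation from negative residuals.** Positive residuals are
  peak-contaminated; the RMS of the negative residuals over not-yet-stripped
  points estimates the noise scale without that contamination.
* **Convergence.** Iterations stop when the fitted curve's RMS change drops
  below `tolerance` (default 0.5%) of its dynamic range *and* the noise
  scale has stabilized to the same relative tolerance, or when no point is
  stripped (a fixed point). The curve-change criterion alone goes quiet
  several iterations before the fit stops descending, which leaves a visibly
  elevated baseline; requiring the noise scale to settle -- the quantity the
  algorithm's original description monitors -- runs the iteration to its
  fixed point (typically 10--30 iterations here, capped at 100 with a
  `converged = FALSE` flag rather than an error).

**Known limitation.** Overlapping Lorentzian wings form an inter-band
pedestal: between crowded bands the measured signal never returns to the true
background, and no peak-stripping polynomial can descend below that lower
envelope. On noiseless synthetic spectra the background is recovered to about
2% RMS of its range and the isolated 1004 cm^-1 band to within 5%, but bands
in crowded regions (883, 1127, 1197 cm^-1) carry a systematic deficit of up
to ~10--15% of their apex after correction. The bias is common-mode across
groups -- between-group intensity *ratios* at the effect bands survive
correction to within ~3% -- which is why downstream group comparisons and
classification are unaffected. The test suite asserts exactly these
properties.

Negative post-correction intensities are retained by default (clipping is
available but breaks the linearity that area normalization relies on).

# Normalization and averaging

`normalize_area()` divides by the trapezoid-rule integral over the native
grid, making each spectrum a density per cm^-1 with unit integral (enforced
to 1e-9 in tests). Each replicate is corrected and normalized *before* the
per-sample average (`preprocess_cohort()` default): a bright replicate then
contributes direction, not weight. The alternative order (average corrected
replicates, then normalize) is available as `normalize_after_average = TRUE`;
the source study does not state which it used. Spectra must share the grid
exactly -- resampling is out of scope.

# Band statistics

Band intensities are the in-window maximum over `position +/- 5` cm^-1 (ties
to the lowest wavenumber), which tolerates small calibration shifts and
off-grid band centers; the exact extraction rule used in the original study
is not stated. Group comparisons follow the decision tree: Shapiro--Wilk per
group, then (if all normal at alpha = 0.05) Levene's test -- classic
mean-centered variant, with the median-centered Brown--Forsythe form as an
option -- routing to one-way ANOVA, Welch's ANOVA, or Kruskal--Wallis. The
same alpha serves the assumption tests and the final call, and no
multiple-testing correction is applied across the 14 bands, matching the
original presentation; `p_adjust = "BH"` is available. Substrate QC uses the
sample (n-1) RSD and the concentration-normalized enhancement factor
$(I_\mathrm{SERS}/c_\mathrm{SERS})/(I_\mathrm{ref}/c_\mathrm{ref})$.

# PLS and component selection

`fit_pls()` is NIPALS PLS2 on mean-centered spectra against mean-centered
one-hot class indicators (PLS-DA). No unit-variance scaling is applied:
normalized spectra already share a scale, and variance scaling would inflate
quiet spectral regions. Scores are orthogonal by construction (asserted to
1e-8 relative); extraction stops early with a warning on rank deficiency.

The component count comes from the cross-validated MSEP curve
(`compute_msep_curve()`, N = 0 is the class-mean baseline) and the adjusted
Wold rule (`select_components()`): keep adding components while the relative
improvement $(\mathrm{MSEP}_{N-1} - \mathrm{MSEP}_N)/\mathrm{MSEP}_{N-1}$ is
at least 5%, stop at the first failure, floor at one component. The original
description ("a new component must improve prediction significantly, 5%") is
ambiguous between this relative-improvement form and the ratio form
$\mathrm{MSEP}_N/\mathrm{MSEP}_{N-1} > 0.95$; the two are algebraically the
same rule, so a single implementation covers both readings. The rule is
monotone in the threshold (a property test asserts this).

On cohorts with planted latent structure the selector recovers the truth: we
validate it on four-class cohorts whose class information lives in exactly
three orthogonal latent factors of decreasing strength (a four-class design
is required -- with three classes the centered indicator matrix has rank two
and a third component is not identifiable from prediction error).

# RBF-SVM, cross-validation and reporting

The SVM uses the Gaussian radial kernel
$K(u, v) = \exp(-\lVert u - v\rVert^2 / 2\sigma^2)$ (libsvm through e1071,
`gamma = 1/(2\sigma^2)`, no internal rescaling). The (C, sigma) grid defaults
to $C \in 2^{-5}, 2^{-3}, \dots, 2^{15}$ and
$\sigma \in 2^{-4}, \dots, 2^{4}$; accuracy is evaluated with stratified,
seeded 10-fold CV at the sample level (one averaged spectrum per sample, 90
units), ties broken toward the smallest C then the smallest sigma. Multiclass
predictions aggregate the pairwise (one-vs-one) decision values by majority
vote; vote ties go to the largest summed signed decision value, then to class
order. The OVX-vs-rest decision score (the signed sum of pairwise decision
values involving OVX) feeds a rank-based ROC whose trapezoidal AUC equals the
Mann--Whitney statistic and is invariant under monotone transforms.

**Single-level vs nested protocol.** By default `run_pls_svm()` follows the
study's protocol: PLS and component selection on the full data, grid search
and the reported accuracy sharing the same folds. That estimate is
optimistically biased -- the reported accuracy is the maximum of ~100
correlated CV accuracies, and the supervised PLS projection has seen every
sample. On data with *no* group signal this bias alone produces ~40--45%
"accuracy" against a 33% chance level. `nested = TRUE` therefore redoes
every data-dependent choice (PLS fit, component count, hyper-parameters)
inside each outer training fold; the chance-level recovery check in the
acceptance suite uses this unbiased estimator, and honest generalization
claims on real data should too.

# Problem sizes and numerical choices

The shipped checks run at desk scale, chosen as the package's own test
design: the full default cohort (900 spectra) for end-to-end runs, 50 seeded
cohorts for the effect-significance rate, 100 seeded latent cohorts for
component-selection recovery, 20 seeded null cohorts (reduced 5 x 4
hyper-parameter grid, nested CV) for the chance-level check. Degenerate
inputs fail loudly with labelled errors (zero-area spectra, mismatched grids,
missing manifest files, single-class responses, sub-3-sample groups); rank
deficiency and non-convergence set flags instead of raising.

# Reproducibility

Every stochastic step (generation, fold assignment) derives from one root
seed through fixed sub-streams; `run_pipeline()` writes a run manifest with
the parameter snapshot, seed and artifact checksums, and rerunning with the
same configuration reproduces byte-identical metrics. The numbered scripts
under `analysis/` execute the four stages in order and narrate what they
find; `scripts/acceptance.R --seed S --out results/acceptance.json`
recomputes the headline quantities from scratch.
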