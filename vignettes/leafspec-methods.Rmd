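---
title: "Methods: leaf-level hyperspectral analysis under elevated CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf-level hyperspectral analysis under elevated CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspec)
```

`leafspec` analyses leaf-clip reflectance campaigns from forest CO2
enrichment experiments. This vignette documents the models and procedures,
the tunable parameters and their defaults, the numerical choices, and what
the built-in simulator does and does not emulate.

## Preprocessing model

A field spectroradiometer of the class used for canopy work records each
spectrum on three detectors — VNIR (350–1000 nm, ~1.5 nm sampling), SWIR1
(1000–1890 nm, ~3.8 nm), SWIR2 (1890–2500 nm, ~2.5 nm) — which overlap near
their boundaries. Preprocessing has three steps.

**Stitching.** The detectors disagree slightly in the overlap windows, and
the instrument literature offers no single convention, so `stitch()` exposes
two explicit policies. The default, `"cut"`, assigns each wavelength to the
detector that nominally owns it (VNIR below 1000 nm, SWIR1 from 1000 to
below 1890 nm, SWIR2 from 1890 nm): deterministic, value-preserving, and the
common field-spectroscopy practice. The `"rescale"` policy first applies a
multiplicative jump correction — each later segment is scaled so its mean
over the overlap window matches the mean of the already-corrected earlier
segment — and then cuts. Both policies are policy-invariant when the
detectors agree exactly on the overlap; the choice is surfaced to the user
rather than hidden. A gap above 5 nm between detector ranges is an error.

**Resampling.** The stitched series is linearly interpolated onto the
inclusive integer grid 350..2500 nm (2151 points). Linear interpolation is
chosen over splines because it cannot overshoot (reflectance stays inside
the hull of neighbouring samples) and the native sampling (≤3.8 nm) makes
the interpolation error negligible at 1 nm. Beyond the measured range the
edge value is held; coverage short of the grid by more than 5 nm errors.
Resampling is idempotent.

**Absolute reflectance.** Leaf-clip instruments measure reflectance relative
to an internal reference panel; absolute reflectance is relative reflectance
multiplied by the panel's laboratory-calibrated reflectance curve,
interpolated to the grid. Reflectance is stored as a fraction throughout;
percent appears only at I/O edges. Values above 1 can legitimately occur in
leaf-clip geometry, so they are retained and flagged (clipping only at 0 and
at a hard ceiling of 1.5) rather than silently truncated.

## Vegetation indices

The eight indices (NDVI, MCARI, PRI, PSRI, NDNI, NDLI, NDWI, NPQI) are
computed from single bands ρλ on the 1 nm grid; a non-integer request is
rounded to the nearest nanometre. NDNI and NDLI are log-reciprocal
normalised differences; the implementation uses the natural log, and the
difference-over-sum structure makes the value invariant to the log base.
A zero denominator or a nonpositive band under a logarithm yields a
*flagged undefined* value, which downstream models drop listwise with a
reported count — never silently. Integrated reflectance is the trapezoidal
integral over the grid (within rounding, the plain 1 nm sum), in units of
fraction·nm: a flat spectrum of 0.2 integrates to 430. The trapezoid was
chosen because it is stable under grid refinement.

## PCA

`pca_fit()` centres and, by default, unit-variance scales each wavelength
before a singular-value decomposition (`prcomp`). Standardised PCA matches
the default of the analysis software family commonly used for such campaigns,
but both conventions appear in spectroscopy — brightness-dominated,
centre-only PCA concentrates far more variance in PC1 — so the flag
`standardize = FALSE` is provided and the acceptance script reports the
variance shares under both. Zero-variance wavelengths are dropped before
scaling (with a message) and restored as zero loadings. Component signs are
fixed by making each component's largest-magnitude loading positive, so
scores and loadings are reproducible run to run.

## PLSDA

Treatment discrimination uses PLS1 regression of the centred/scaled spectra
matrix on the dummy-coded class (aCO2 = 0, eCO2 = 1), fitted by NIPALS
deflation; a spectrum is predicted eCO2 when its continuous prediction
reaches 0.5 — the standard threshold for dummy-coded two-class PLSDA.
`plsda_tune()` makes a stratified 70/30 train/test split, runs stratified
k-fold cross-validation (default tenfold) on the training portion only over
component counts up to 60, selects the count with maximal CV accuracy
(plain argmax; ties break towards fewer components — a one-standard-error
rule is deliberately not used), refits on the full training set, and only
then touches the held-out 30%. Both the CV-curve maximum and the held-out
accuracy are reported separately, since they estimate different things.
The split and the folds are pure functions of one seed.

Held-out performance is summarised with the confusion matrix, an exact
Clopper–Pearson 95% interval on accuracy, a one-sided exact binomial test
of accuracy against the no-information rate (the larger class frequency),
and McNemar's test computed exactly as a two-sided binomial on the
discordant pairs (the continuity-corrected chi-square approximation is
avoided; at 5 vs 5 discordants the exact test returns p = 1).

**Wavelength importance.** No single formula is canonical for "cumulative
wavelength importance" in PLSDA, so the package declares one:
importance(λ) = Σ_k |w_λk| · v_k over the retained components, where w_k is
the k-th X-weight vector and v_k the fraction of class-code variance
explained by component k, normalised to max 1. Weighting |w| by v_k makes
the profile cumulative over components while discounting components that
explain little of the class code. The raw per-component weights are kept on
the model object so alternative definitions can be computed from the same
fit. Wavelengths dropped as zero-variance re-enter with importance 0.

## Mixed models

Every response (each index, integrated reflectance, each PC score) is fitted
with the study model

    response ~ CO2 + (1 | Tree) + (1 | Tree:Date)

by REML with Satterthwaite degrees of freedom, via `lme4`/`lmerTest` — the
same estimation machinery practitioners use directly. aCO2 is the reference
level, so the intercept is the aCO2 mean and the treatment coefficient the
eCO2 effect. With two arrays per treatment and two trees per array the
treatment test is tree-limited: its Satterthwaite df lands near 6, which is
why campaign-scale effects need to be large to reach significance. Variance
components are reported for tree, tree-by-date, and residual (leaf) levels;
with one observation per tree-date cell the tree:date and residual
components are only weakly identified, and boundary (zero) estimates are
returned flagged (`singular`), not errored. lme4's gradient/Hessian
check messages near such boundaries are recorded on the fit object as
convergence diagnostics. A constant response short-circuits to a degenerate
zero-variance fit. The array level is available as an optional extra random
intercept (`include_array = TRUE`) but is off by default: nested below
treatment with two arrays each, it is rarely identifiable and in the
motivating design explains no variance beyond tree identity.

The "multivariate" summary across the first four PCs is implemented as a
pooled model on the stacked standardised scores with a single intercept and
a single treatment effect, alongside the four univariate fits. A fully
multivariate formulation (per-PC residual variances, cross-PC correlations)
would estimate a different quantity; since a single shared effect is what is
conventionally reported for this design, the stacked form is used and both
the pooled and univariate results are returned, labelled as such.

## The campaign simulator

`simulate_campaign()` generates labelled campaigns so every stage is
testable without field data. The leaf model is deliberately simple:

    R(λ) = P(λ) · exp(−Σ_i c_i A_i(λ)) + ε(λ)

with a smooth envelope P (level 0.384, curvature 0.90 around a 950 nm NIR
centre), Gaussian absorbance features per constituent (chlorophyll 430 and
680 nm; carotenoids 460 and 500 nm; water 1450 and 1940 nm; dry matter
1720, 2100, 2300 nm), abstract concentrations c_i, and white spectral noise
(SD 0.004). Concentrations vary multiplicatively: independent Gaussian
effects per pigment on the log scale at the tree (SD 0.056), tree-by-date
(SD 0.064), and leaf (SD 0.17) levels. Log-scale effects guarantee
positivity and mimic multiplicative biology; they are drawn independently
per pigment because a shared draw would cancel out of ratio-type indices.
The default eCO2 effect multiplies the carotenoid mean by 1.17, i.e. shifts
the carotenoid:chlorophyll ratio, the mechanism that makes PSRI — which is
sensitive to exactly that ratio — the responsive index.

No pigment concentrations are reported for the motivating campaigns, so the
defaults cannot be anchored to measurements. They were instead calibrated
once, numerically, so that the *index-scale* behaviour lands in the
magnitude bracket such campaigns print: integrated reflectance in the low
400s (fraction·nm), PSRI near zero under aCO2 with an injected eCO2 effect
of ≈ +0.026, and PSRI-scale variance components of ≈ 1e-2 / 1.5e-2 / 4e-2
SD for tree / tree-by-date / leaf, with the leaf level dominant. The
default design is 2 treatments × 2 arrays × 2 trees × 4 dates × 30 leaves
(960 spectra; `n_total_per_treatment` trims to realized unbalanced totals
such as 469/463).

Seeding is splittable: one campaign seed derives a per-tree stream (tree and
date effects) and a separate per-tree leaf stream, so enlarging the leaf
count never perturbs tree effects, and identical seeds give bit-identical
campaigns.

**What the simulator does not emulate** — and hence what passing tests do
not show about field data: real oak optics (no radiative-transfer layer
structure, no specular or surface effects, no anthocyanins or senescent
browning), seasonal trends (dates differ only through random tree-by-date
effects, not a phenological trajectory), wavelength-correlated instrument
noise, detector-boundary artefacts, or herbivory and within-canopy light
gradients. Conclusions about the pipeline's statistical behaviour transfer;
conclusions about oak spectra do not.

## Numerical choices and degenerate inputs

- Interpolation is linear everywhere (resampling, panel curves); ties in
  component selection go to the smaller count; PCA/PLSDA sign and split
  determinism are fixed by explicit rules and one seed.
- Detector segments may protrude up to 40 nm past their nominal boundary
  (real detectors overlap); a sweep extending far beyond one detector's
  range is treated as an already-merged full-range series.
- A duplicated wavelength within a file is a parse error naming the
  wavelength; a strict wavelength decrease is interpreted as the start of
  the next detector sweep.
- Undefined index values propagate as flagged missing and are dropped
  listwise per model with a logged count.
- Reported problem sizes: the test suite exercises the full 960-spectrum
  design end to end, 200 null campaigns for type-I calibration, 100
  replicates for effect-coverage, and 50 for variance-component recovery —
  sizes chosen to keep Monte-Carlo error well below the tolerances tested
  while the whole suite stays fast on one CPU.

## Known limitations

- The SVC-style reader implements a documented two-column dialect with a
  `key= value` header block, not the full proprietary header layout;
  campaign-specific adapters can stay outside the package as thin shims.
- PLSDA is two-class only, with no sparse or penalised variants.
- The mixed-model layer fits exactly the study's nested random-intercept
  structure (plus the optional array level), not arbitrary formulas.
- Real-data reproduction of any particular campaign requires that
  campaign's deposited spectra; the package's own guarantees are the
  property-based ones in the test suite.
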