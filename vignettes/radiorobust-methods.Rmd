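---
title: "Methods: quantifying and correcting PET radiomic feature robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and correcting PET radiomic feature robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiorobust)
```

## The problem

Radiomic features — quantitative descriptors of intensity, shape and texture
computed over a volume of interest (VOI) — are attractive PET biomarkers, but
many of them shift when the same activity distribution is acquired or
reconstructed differently. Before pooling radiomic data across imaging
protocols one needs to know, per feature and per acquisition/reconstruction
parameter: is the feature robust; if not, is its parameter dependence simple
enough to remove with a closed-form correction; and how much of the residual
variability is really driven by the region's volume and intensity rather
than the parameter itself.

`radiorobust` implements that full analysis as a reproducible pipeline driven
by a digital image-quality phantom, so the method can be developed, tested
and calibrated without scanner data.

## The setting grid

Nine investigation groups each vary one parameter and hold the rest at fixed
values: acquisition time (11 levels, 1–15 min/bed), transaxial matrix size
(128–384), z-axis filter (None/Light/Standard/Heavy), Gaussian post-filter
width (0–10 mm in 0.5 mm steps), penalised-likelihood β (50–1000), the 24
OSEM iterations×subsets combinations, their two marginal views (8 iteration
counts, 3 subset counts, each averaged over the other dimension), and 6
reconstruction algorithm variants — 94 settings in total. `build_grid()`
freezes this grid; custom group definitions can be passed through
`investigation_groups()`-shaped lists.

For curve fitting, z-filters are encoded by their kernel weight
(None→1, Light→2, Standard→4, Heavy→6) and some x-axes are rescaled to keep
the reciprocal/log model families away from singularities: acquisition time,
z-filter weight and iteration counts are multiplied by 10, Gaussian widths
are shifted by +2 mm (`rescale_x()`). The rescaling is monotone and
invertible on every level set, so it changes coefficients, not fits.

## The digital phantom and the reconstruction surrogate

`phantom_spec()` describes a NEMA-IQ-style body: six spheres of 37, 28, 22,
17, 13 and 10 mm inner diameter on a 114.4 mm circle, a 50 mm cold central
"lung" cylinder, and a warm background, with a 4:1 sphere-to-background
activity ratio (20 vs 5 kBq/mL; the background value is implied by the
ratio, not an independent measurement). Sphere centre coordinates, the
2.78 mm slice thickness and the 180 mm axial extent are package choices —
plausible for the scanner class but not published values — and are
configurable. Boundaries are rasterized with 4³ subvoxel supersampling,
which keeps interior-mean errors below 1% at a 256 matrix.

`simulate_reconstruction()` is explicitly an image-domain surrogate, not a
reconstruction: it must reproduce the *directions* of the real effects with
controllable first and second moments, not scanner-accurate magnitudes. Per
setting it applies, in order:

1. trilinear resampling to the setting's matrix grid;
2. 3D Gaussian smoothing with FWHM combining, in quadrature, an intrinsic
   resolution (4.5 mm; divided by 1.05 when PSF modelling is on), the
   explicit post-filter, and a penalisation term
   `7·(1 − exp(−β/350))` mm for BPL-type algorithms;
3. a three-point axial kernel `[c−1, c+1, c−1]/(3c−1)` with `c` the encoded
   z-filter weight — the identity at `c = 1` and monotonically heavier
   axial smoothing as `c` grows;
4. additive Gaussian noise with
   `σ = 0.5 · √(3/t) · (updates/56)^0.5 · 0.85^[TOF]` kBq/mL.

The β and z-filter forms were chosen so that heavier penalisation and
heavier axial filtering always smooth more — the physically correct
monotonicity for penalised-likelihood reconstruction and axial filtering —
and the updates exponent makes later OSEM updates noisier, as in practice.
Noise is additive Gaussian *after* smoothing (post-reconstruction PET noise
is approximately Gaussian, and the analysis only consumes means and
variances); it is white, whereas real reconstructed noise is spatially
correlated. Together with the absence of attenuation, scatter and sinogram
statistics, this is the main sense in which passing tests here do not
certify behaviour on real scanner data: the pipeline's *statistical
machinery* is fully exercised, the *physics* is a controlled stand-in.

A consequence worth noting: partial-volume behaviour is real in this
surrogate (small-sphere means fall with smoothing; the 37 mm sphere core is
preserved), but a full centre-in VOI mean of even the largest sphere is not
invariant under 10 mm smoothing — boundary voxels necessarily lose
activity. Mean-preservation checks therefore use the half-radius core.

## Feature extraction

`extract_features()` computes the standard 107-feature set per VOI: 14
shape, 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM and 5 NGTDM
features, following the IBSI-style formulations used by the common Python
extractor. No R implementation of this feature set exists in the supported
stack, so the extractor is implemented here and validated against
brute-force re-computations (co-occurrence/dependence enumeration, run and
zone construction) and closed forms (constant VOIs, analytic sphere
geometry) in the test suite.

Conventions fixed by the analysis: intensities are discretized to a fixed
bin number of 64 over the VOI's own min–max range; GLCM and GLRLM matrices
are summed over the 13 unique 3D directions (26-connectivity) with a
single-voxel GLCM offset, which after normalisation equals averaging the
per-direction matrices; feature names are family-qualified
(`glcm_Contrast`) because several families reuse short names. Shape
features come from a marching-tetrahedra mesh of the binary mask: with
binary vertex values every tetrahedron is cut by the plane where the inside
barycentric mass equals 1/2, so volume fractions (1/8, 1/2, 7/8) and cut
areas have exact closed forms. The staircase mesh slightly overestimates
the area of smooth surfaces (sphericity of a rasterized sphere ≈ 0.79
rather than ≈ 1), a known property of isosurfaces of binary masks; it is
consistent across settings, which is what the robustness analysis needs.

A texture family is marked invalid for a VOI when the discretized VOI has
fewer than 2 voxels or its matrix cannot be formed, and undefined values
(0/0 entropy ratios and the like) are flagged per feature. `filter_invalid()`
then excludes a (feature, region) pair from *all* levels of a group if it is
invalid at any level — the regions×levels table must stay complete for the
ICC — and logs every exclusion. On coarse grids the 10 mm sphere loses its
texture families exactly the way the smallest sphere does at a 128 matrix
in practice.

## Robustness

For a feature and group, each region's values across levels give a
within-region percentage CV (`100·sd/|mean|`); their mean across regions is
`CV_mean`. Regions whose mean is negligible against the spread (skewness
and similar sign-crossing features) make percentage CVs meaningless and are
dropped with a flag rather than propagated. Agreement is a two-way,
single-measurement, absolute-agreement ICC (McGraw–Wong A,1) with regions
as subjects and levels as measurements:
`(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))`. This variant is the
natural reading of "agreement between measurements from a two-way model";
negative estimates are reported as computed but always classify as
non-robust, and a feature is robust iff `CV_mean < 10%` and `ICC > 0.90`.
The ICC implementation is checked against an independent `aov`
mean-squares decomposition to 1e-10.

## Correction

Eight candidate forms `α·g(x)+β` with
`g ∈ {x, x², x³, 1/x, 1/x², 1/x³, log x, 1/log x}` are fitted to the mean
response across regions. "Iteratively reweighted least squares with
intrinsic weights" reduces, for a model linear in (α, β) with weights fixed
at the reciprocal across-region variance per level, to a single weighted
solve — the iteration has nothing to update — so that is what
`fit_candidates()` does, in closed form. Zero-variance levels are capped at
10⁶× the median weight instead of receiving infinite weight. Natural
logarithms are used throughout; the base only rescales α. The best family
minimises `AIC = n·ln(RSS_w/n) + 2k` with `k = 3` (α, β, residual scale);
constants shared by all candidates are dropped, exact ties resolve to the
simplest transform and are logged. Families whose transform is undefined at
a level (e.g. `1/log x` at `x = 1`) are inadmissible rather than silently
refitted.

Correction applies the rearranged best fit, `(value − β)/g(x)`, per region
with the group-level β. Data generated exactly from a family with a shared
offset correct to constants — post-correction CV of 0 — which the test
suite verifies for all eight families, along with ≥90% AIC family recovery
at noise equal to 2% of the response range. Pre/post per-region CVs are
compared with a one-sided exact Wilcoxon signed-rank test; ICC improvement
is necessarily a point comparison because one ICC exists per feature×group
(the pairing a rank test would need is undefined for a single value — a
deliberate, flagged reading). Significant CV reduction with ICC improvement
makes a feature *correctable* if the corrected values meet the robust gate,
*moderately correctable* otherwise; anything else is *not correctable*. The
algorithm group is categorical and never enters correction.

## Attribution to volume and intensity

Per feature×group, `fit_feature_effects()` fits a linear mixed model of the
(z-standardized) feature value on the standardized parameter, region mesh
volume (`shape_MeshVolume`) and region mean intensity (`firstorder_Mean`),
with per-region random intercepts and random parameter slopes; the
categorical algorithm group uses level contrasts with intercept-only random
structure. Standardizing response and predictors makes coefficients
comparable across features (needed for any cross-feature display) and
invariant to unit changes; p-values use the Satterthwaite approximation.
One reading decision: for categorical predictors the random structure is
per-region (the per-feature alternative would conflict with fitting one
model per feature); the record is flagged `categorical` and its parameter
coefficient marked non-comparable in spirit. Type-I error for a null
intensity effect sits near the nominal 5% in the calibration suite.

## Summaries

Robust (or correctable ∪ moderately-correctable) indicators are summarised
with logistic mixed models with feature-specific random intercepts; each
feature's predicted probability `PP = 1/(1+e^−(b+aX+u_feature))` includes
its random intercept, and groups are summarised as median [IQR] of the
per-feature PPs. Completely separated levels (all-0/all-1) are flagged and
reported at the boundary. Groups are compared pairwise on their per-feature
PP vectors with a two-sample Cramér–von Mises permutation test — full
enumeration when the split count is ≤ 1e5, otherwise seeded Monte-Carlo
with the (b+1)/(B+1) estimator; the default 9999 permutations resolve
p-values below 0.05/36 — under Bonferroni adjustment over all pairs. The
statistic is rank-based (invariant under monotone transforms); ties are
handled by evaluating the pooled ECDFs at tied-block ends identically for
observed and permuted splits. Volume/intensity influence is condensed into
odds ratios by a logistic mixed model contrasting the significance
indicators of volume (or intensity) against the parameter per feature; this
indicator-contrast model is one consistent construction, not a published
specification, and is documented as such. Separation yields a flagged,
unbounded CI rather than a numeric artefact.

## Pipeline, problem sizes and determinism

`run_all()` executes grid → simulate → extract → filter → robustness →
correction → attribution → summaries, writing each stage as long-format CSV
plus a JSON manifest. Every stochastic stage draws from a seed derived from
the master seed and a named substream label, so two runs with one master
seed are byte-identical — which the acceptance suite checks with file
hashes. The two marginal OSEM groups are derived from the 24 updates
reconstructions by averaging (`aggregate_nuisance()`), not re-simulated,
mirroring how a single set of reconstructions is re-read per margin.

The default `image_scale = 0.5` simulates on half-size grids (e.g. 128
instead of 256, with proportionally thicker slices). This is the package's
default working scale: it preserves every structural property the pipeline
analyses (relative voxel counts, invalid small-sphere behaviour, monotone
parameter effects) while keeping a full 94-setting run around a minute on
one core; `image_scale = 1` reproduces the nominal acquisition geometry at
roughly 8× the cost. Test-suite simulations use 128–256 grids and the
statistical calibrations use 100–500 replicates for the same reason:
large enough for stable Monte-Carlo checks, small enough to run routinely.

## Known limitations

- The effect simulator is a surrogate: no sinogram statistics, attenuation,
  scatter or spatially correlated noise; magnitudes are plausible, not
  calibrated to a scanner.
- Surface-derived shape features carry the staircase bias of binary-mask
  meshes; they are internally consistent but not IBSI-benchmark-exact.
- The odds-ratio construction and the ICC "improvement" gate are documented
  readings of underdetermined analysis choices.
- Percentage CVs are undefined around zero means; such regions are dropped
  per feature with a logged flag, which can reduce the effective region
  count for sign-crossing features.
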