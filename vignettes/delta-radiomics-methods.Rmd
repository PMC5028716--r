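---
title: "Methods: delta-radiomics response phenotyping with deltarad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-radiomics response phenotyping with deltarad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

deltarad implements a delta-radiomics screen for a binary treatment-response
label. Each subject contributes a baseline and a follow-up CT scan of one
lung lesion, with a co-registered binary mask, plus a mutation label
(1 = TKI-sensitising mutant, 0 = wild-type). The pipeline:

1. reads image/mask pairs (NIfTI or NRRD), validates their geometry and
   optionally resamples them to isotropic resolution;
2. extracts a fixed catalogue of 183 radiomic features per scan;
3. forms the *delta* table, defined as baseline minus follow-up values,
   feature by feature;
4. keeps the 15 most variant delta features by coefficient of variation,
   prunes those whose pairwise rank correlation exceeds 0.95, and appends
   tumor volume and maximum diameter for comparison;
5. scores each selected feature's ability to separate the two label groups
   with the ROC AUC and a two-sided Mann-Whitney test, at baseline,
   follow-up and delta;
6. separately, quantifies test-retest stability of every feature as a
   one-way intraclass correlation over same-day repeat-scan pairs.

Because no clinical scans ship with the package, a synthetic lesion-phantom
generator provides study-shaped data for validation, and all quantitative
claims made by the test suite are claims about those phantoms.

# Feature catalogue

The default manifest expands to exactly 183 features. The total is fixed;
the composition is a design decision of this package, built from the feature
classes below with parameter grids chosen to cover each class's natural
range at desk scale:

* **Size/shape (12)** - `Volume` (voxel count x voxel volume, mm^3),
  `Max_Diameter` (largest surface-to-surface Euclidean distance, mm),
  `Boundary_Radius_Std` (population SD of centroid-to-surface distances,
  mm; zero for a sphere), and `Shape_SI1..SI9`.
* **Sigmoid margin (6)** - offset, slope and amplitude means at line
  half-lengths 3 and 5 mm.
* **Laws energies (14)** - all zero-mean 5x5 kernels from the Level,
  Edge, Spot, Ripple and Wave basis vectors.
* **Gabor energies (16)** - orientations {0, 45, 90, 135} degrees x
  wavelengths {3, 5, 7, 9} pixels.
* **Co-occurrence (135)** - 15 statistics x distances {1, 2, 4} voxels x
  aggregations {mean, std, range} over the 13 unique 3D directions.

## Laws and Gabor energies

Both are 2D in-plane filters applied to every axial slice, matching the
axial acquisition geometry of CT; the energy is the sum of squared filter
responses over lesion voxels, so both classes are homogeneous of degree 2
in image intensity. The Laws bank contains the 10 symmetrised
cross-products `(u'v + v'u)/2` of distinct basis vectors - ordered LE, LS,
LR, LW, ES, ER, EW, SR, SW, RW as ids 1-10 - followed by the four zero-mean
self-products EE, SS, RR, WW (ids 11-14). The pure-level kernel is excluded
because its response does not vanish on constant images. The Wave vector is
taken as the standard `W5 = (-1, 2, 0, -2, 1)`. Filter ids are stable and
documented so that externally numbered filters can be mapped by name.

Gabor filters use the real (even) part of an isotropic-envelope Gabor
kernel; the envelope width follows the one-octave bandwidth convention
`sigma = lambda/pi * sqrt(ln 2 / 2) * (2^b + 1)/(2^b - 1)`. The kernel is
not DC-corrected: a small response to constant offsets is accepted and
irrelevant in practice because energies are compared within a cohort
imaged on one HU scale. Wavelengths and orientations are in pixel/degree
units in the axial plane.

## Co-occurrence statistics

Intensities inside the mask are quantised into 32 equal-width bins over
the lesion's own intensity range (the binning convention most common in
radiomics toolkits). Pairs are counted at offset
`distance * direction` for the 13 unique 3D directions, symmetrised, and
normalised. The statistic set is the classical Haralick family (angular
second moment through the informational measures of correlation) plus the
maximum correlation coefficient and dissimilarity - 15 statistics. The
distance multiplies the integer direction vector (a Chebyshev-style
offset), so "distance 4" pairs diagonal voxels 4 steps apart along each
involved axis; normalising the direction to unit length and rounding was
rejected because it collapses distances 1 and 2 onto the same offset for
10 of the 13 directions.

Degenerate matrices never produce `NaN`: with a single occupied grey
level, correlation falls back to 0, IMC1 to 0 (its entropy denominator
vanishes) and MCC to 1 (the rank-one limit of the Q matrix); an all-empty
pair set flags the matrix as degenerate and the same fallbacks apply.

## Shape index

The mask indicator is smoothed with an isotropic 1.5 mm Gaussian and the
principal curvatures `k1 >= k2` of the implicit surface are evaluated at
every surface voxel from closed-form expressions in the gradient and
Hessian. Curvature is signed so that a convex lesion is positive, and the
index `s = 1/2 + (1/pi) atan2(k1 + k2, k1 - k2)` maps to [0, 1] with
spherical cups at 0, saddles at 1/2 and spherical caps at 1; a digitised
ball therefore concentrates in bin 9, and the saddle-ridge range falls in
bin 6. `SI1..SI9` are the surface fractions of nine equal-width bins and
always sum to one. Surface voxels with vanishing gradient (flat or
degenerate patches) are assigned to the central bin rather than dropped.
The 0-to-1 range follows the feature-table convention of the source
catalogue rather than Koenderink's [-1, 1]; the affine map between the two
preserves the binning.

## Sigmoid margin profiling

For up to 100 surface voxels (an evenly spaced, deterministic subsample in
array order), a line is drawn along the outward normal (the negated
gradient of the smoothed indicator), and the image is sampled trilinearly
every 0.5 mm over +/- the half-length. The logistic model
`f(t) = B + A/(1 + exp(-s (t - t0)))` is fitted by Levenberg-Marquardt
least squares, initialised with `B + A` at the inner plateau mean, `B` at
the mean of the outermost 20 % of samples, `t0 = 0` and
`|s| = 4/half_length` oriented to decay outward. Constant profiles
short-circuit to `A = 0`. Per line the offset is the mid-transition
density `B + A/2`, the slope is the maximum density change rate
`|s A|/4` in HU/mm, and the amplitude is `|A|`; features are means over
fitted lines, and lines leaving the volume or failing to converge are
skipped and counted. On noise-free phantoms the recovered offset matches
the mid-density between lesion and parenchyma to a few HU, and the slope
decreases strictly with the generated margin width - the package's
operational definition of margin sharpness.

# The synthetic cohort

The generator voxelizes a continuous lesion model: an ellipsoid with
per-axis semi-axes, a band-limited angular surface perturbation (direction
harmonics of degree at most 3, at most four lobes, amplitude `bumpiness`
as a fraction of the radius), a logistic radial density transition of
width `margin_width` between the parenchyma (-780 HU) and lesion (30 HU)
plateaus, an intralesional texture field (white noise smoothed with a
Gaussian of width `texture_corr_len`, rescaled to `texture_sigma` = 40 HU),
and i.i.d. scan noise (20 HU). Default grid: 64^3 voxels at 1 mm isotropic;
semi-axes are drawn uniformly from 5-15 mm per subject. All outputs are
pure functions of the seed.

Treatment response scales the follow-up radii by `ratio^(1/3)` with
`ratio` drawn log-normally - `meanlog = log 0.55, sdlog = 0.25` for
mutants, `meanlog = log 0.98, sdlog = 0.08` for wild-type - so mutant
lesions shrink to roughly 57 % of their volume on average while wild-type
lesions are essentially stable. Mutants additionally get a 1.6-fold wider
margin and a 1.5-fold longer texture correlation length, emulating the
blurring, regressing phenotype of responders. Clinical effect sizes for
these response components are not publicly available at the per-lesion
level, so these are calibrated, fixed modelling choices, not fitted
values.

Test-retest pairs share the lesion model - geometry, plateaus and the
texture field, which is sampled in the lesion frame so it translates
rigidly - and differ only by an independent noise realisation and a
sub-voxel rigid shift drawn uniformly from half a voxel per axis.

What the phantoms do *not* emulate: lung anatomy and vasculature,
reconstruction-kernel and scanner effects, segmentation variability
(masks are exact by construction), and longitudinal changes other than
size/margin/texture scaling. Passing tests therefore demonstrate the
correctness and stability of the computational pipeline under known
ground truth, not clinical performance.

# Statistics

The AUC uses the Mann-Whitney identity `U/(n_pos n_neg)` with ties counted
1/2 and label 1 as the positive class; it is reported directionally (values
below 0.5 mean mutants run lower). Significance is the two-sided
Mann-Whitney test: exact enumeration for tie-free data with
`n_pos * n_neg <= 400`, otherwise the tie-corrected normal approximation
with continuity correction. The two agree to better than 0.01 for balanced
groups of 10 or more per arm; below that the exact test's discreteness
dominates and the exact branch is the default anyway. No multiplicity
correction is applied in the primary screen (matching the small fixed
panel it is designed for); a Benjamini-Hochberg column is emitted as
clearly supplementary output.

Test-retest stability uses the one-way random-effects single-measurement
ICC(1,1) `= (MSB - MSW)/(MSB + MSW)` for two replicates - the standard
estimator when the two scans are exchangeable same-protocol repeats.
ICC(2,1) and ICC(3,1) are available by configuration and the estimator
label is recorded in every result row.

Feature selection ranks candidate delta features by coefficient of
variation (sample SD over |mean|; undefined and excluded when the mean is
numerically zero, a guard needed because delta values are signed). The
correlation pruning loop removes, from the worst-correlated surviving
pair, the feature with the larger mean absolute correlation to the
remaining candidates, breaking ties by lower CV and then by name - a
deterministic rule that removes the most redundant feature first and makes
the selection invariant to input column order. Spearman correlation is the
default (Pearson available by option). Volume and maximum diameter never
enter the ranking pool and are always appended for comparison.

# Numerical choices

* Resampling: trilinear for images, nearest-neighbour for masks (keeps
  masks strictly binary); the output grid covers the same world extent to
  within one voxel. The clinical preprocessing target of 0.25 mm is
  supported but the synthetic pipeline stays at 1 mm, where all feature
  maths is spacing-aware.
* Convolutions are separable where the kernel allows (all Laws kernels and
  both terms of the real Gabor kernel), with half-sample symmetric
  ("reflect") boundary handling, computed on the mask's bounding box
  expanded by the kernel half-width.
* World convention: arrays are indexed `(x, y, z)` with axial slices along
  the third dimension; voxel centres sit at `origin + index * spacing`
  (0-based indices), all in mm.
* NIfTI headers store spacing and origin as 32-bit floats; values are
  snapped to 6 (spacing) and 5 (origin) decimals on read so that
  round-trips of ordinary millimetre geometries are bit-exact.
* Maximum diameter scans pairwise distances blockwise and recomputes the
  winning pair directly, so the result is identical to an exhaustive
  search.

# Problem sizes

The validation suite exercises the pipeline at sizes chosen to be
comfortable on a single CPU: 64^3 phantom grids, cohorts of 20 + 20
subjects (the scale of a single-institution pilot study), and 20
test-retest pairs. At these sizes a full 183-feature
extraction takes a few seconds per lesion and the complete study a few
minutes. Under these conditions the default response model yields a delta
volume AUC above 0.9 (and far above the baseline volume AUC), and volume
ICC above 0.99 across repeat-scan pairs - the qualitative pattern the
screen is built to detect.

# Known limitations

* Laws/Gabor filtering is strictly 2D in-plane; heavily anisotropic
  out-of-plane texture is only captured by the 3D co-occurrence features.
* The sigmoid fitter assumes a single monotone transition within the
  sampling window; very thin lesions (margins overlapping from both sides
  inside the window) bias the amplitude downward.
* CV-based ranking is scale-dependent across features by design (it is a
  relative-variability measure); features with near-zero mean delta are
  excluded rather than rescued.
* The exact composition of the 183-feature catalogue is this package's
  reconstruction; only the class structure and the total are fixed by the
  design it follows, and the manifest is data-driven so alternative
  compositions are a YAML file away.
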