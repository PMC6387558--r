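---
title: "Methods: single-subject FDG-PET hypometabolism analysis for Lewy body dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-subject FDG-PET hypometabolism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, parameters and
design choices. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The statistical model

### Voxel-wise GLM against a normative database

A single subject is compared with a database of `N` healthy controls by
fitting, independently at every in-mask voxel,

    uptake ~ intercept + patient_indicator + age

by ordinary least squares over the `N + 1` subjects. The reported statistic
is the *negated* t of the indicator coefficient, so that reduced uptake
(hypometabolism) is positive; only this one-sided contrast is thresholded,
because the clinical question concerns hypometabolism only. Degrees of
freedom are `(N + 1) - 3` with the age covariate and `(N + 1) - 2` without.
Group maps replace the single indicator by one spanning all patients, with
df `(Np + N) - 3`. Age enters as a nuisance covariate because regional
uptake drifts with age and patients are typically older than the database;
the generator can inject a linear age effect, and the suite verifies that
the covariate model absorbs it while the covariate-free model flags an
age-atypical but metabolically normal subject.

When a fit is exact (noise-free phantoms), both the indicator coefficient
and its standard error are zero up to floating-point dust; coefficients and
errors below `1e-10` times the mean absolute response are treated as exact
zeros and the voxel's t is 0, which keeps degenerate fixtures well defined.

### Familywise error and cluster extent

The voxel-level familywise threshold at level `alpha` over `V` in-mask
voxels is the Bonferroni Student quantile `qt(1 - alpha/V, df)`. Bonferroni
was chosen over random-field theory deliberately: it is exactly
implementable and testable (the suite inverts the Student CDF with an
independent root-finder), and it is conservative under the positive spatial
correlation that smoothing induces, which the empirical null-rate property
confirms. The threshold method is recorded on every map.

Suprathreshold voxels are grouped into connected components under
18-connectivity (faces + edges, the common neuroimaging convention;
6 and 26 are available) and components below the extent threshold are
dropped. Extent thresholds quoted in voxels are grid-dependent, so the
package works in physical units: the default `extent_mm3 = 800` corresponds
to k = 100 voxels of 2 mm edge and maps to k = 13 on the 4 mm phantom grid
(ceiling). Components with *at least* k voxels survive; a `strict_gt` flag
gives the strictly-greater reading. Labeling uses deterministic
minimum-label propagation restricted to the foreground bounding box, checked
against a stack-based flood fill.

## Preprocessing

Volumes are smoothed with a separable Gaussian kernel, FWHM 8 mm per axis
(sigma = FWHM / (2 sqrt(2 ln 2)), converted to voxels). Boundaries use
half-sample reflection, which makes the per-axis convolution matrix doubly
stochastic: constants and the total image sum are preserved exactly, so
small phantom grids show no rim artifacts. Kernels are truncated at six
standard deviations and renormalized; a centered impulse reproduces the
closed-form 3-D Gaussian to 1e-6.

The analysis mask contains the voxels whose across-*controls* mean exceeds
0.8 times the mean over positive voxels. Patients are excluded from mask
construction on purpose: patient hypometabolism must not shrink the common
analysis domain. The 0.8 fraction is a stand-in for the implicit masking of
standard neuroimaging software; it is configurable.

Global mean scaling multiplies each volume by `target / mean(in-mask)`,
removing between-subject global uptake variability. The target is 1.0
rather than the grand-mean-50 convention of SPM: every downstream quantity
is a ratio or a t statistic and therefore invariant to the constant, and
unit tissue uptake keeps the phantom algebra readable. Scaling is
idempotent, and it commutes with smoothing exactly when the scaling region
is the full grid (both operators are linear and the smoother conserves the
grid sum); over a brain-interior mask the commutation is only approximate
because smoothing moves mass across the mask boundary.

## The phantom generator

The generator defines the study conditions. The atlas is schematic: 14
analysis ROIs (calcarine, cuneus, superior/middle/inferior occipital,
fusiform, lingual, inferior/middle/superior temporal, precuneus, DLPFC,
posterior cingulate, angular) plus auxiliary premotor/motor,
frontal-eye-field and parietal parcels, all axis-aligned boxes placed with
the correct topological relations (posterior vs anterior, medial vs
lateral, left vs right) inside a midline-symmetric ellipsoidal brain.
Default grid 40 x 48 x 40 at 4 mm (~41,000 brain voxels): large enough for
the FWE threshold and cluster extents to be meaningful, small enough that a
t-map takes well under a second.

Controls have tissue uptake 1.0, an optional linear age modulation of ROI
uptake (slope default 0), a subject-level lognormal global factor
(sdlog 0.15) emulating injected-dose and metabolism differences, and
additive Gaussian voxel noise with sd 0.05 of tissue uptake. The database
emulates the normative cohort the analysis assumes: N = 112, age
64.68 +/- 9.35 years (truncated at 18). Patients multiply template uptake
inside pattern-specific regions by `1 - reduction`:

* **DLB**: occipital 25%, temporo-parietal and fusiform 20%, precuneus 25%,
  DLPFC 15%; posterior cingulate spared (the substrate of the cingulate
  island sign).
* **ADD**: temporo-parietal, posterior cingulate and precuneus 25%.
* **PCA**: occipital 25%, temporo-parietal 20%, frontal eye field 25%,
  all lateralized — the left hemisphere receives the full reduction and the
  right `reduction / asymmetry_factor` (default 6, a strongly lateralized
  posterior process; a factor of 2 halves the contralateral effect).
* **PD**: premotor/motor 20% only.

No quantitative regional effect sizes are published for these conditions;
the 15–30% range is this package's calibration choice, set once to produce
clearly suprathreshold but not saturating t values at the stated noise
level, and not revisited. Noise is additive and stationary (its sd does not
scale with the locally reduced uptake): the simplification is deliberate
and documented, since the t statistics depend on between-subject variance,
not on lesion-local noise scaling.

What the phantoms do **not** emulate: PET physics (scatter, attenuation,
partial volume, reconstruction artifacts), anatomical variability and
registration error, atrophy, and correlated physiological noise. Passing
the property suite therefore demonstrates the correctness of the
statistical machinery under its own assumptions, not clinical performance
on real scans.

## Hallmarks

* **Regional involvement** is undefined in narrative descriptions of expert
  reading; it is implemented as: at least `min_fraction` (default 2%) of
  the composite region's voxels are suprathreshold within a surviving
  cluster. The fraction rule is robust to single stray voxels and monotone
  in its threshold.
* **CIS** is the uptake ratio `mean(PCC) / (mean(precuneus) + mean(cuneus))`
  on the scaled image. Whether the denominator should be the sum of the two
  regional means or the mean over their union is ambiguous in the clinical
  literature; the sum of means is implemented, which yields values in
  roughly (0, 1] — the range on which published cutoffs near 0.8 live — and
  equals 0.5 on a uniform brain. It is invariant to any global
  rescaling, hence to global mean scaling; smoothed images are used since
  CIS is computed after preprocessing.
* **Asymmetry** has no published formula; the package uses the voxel-count
  index `AI = |nL - nR| / max(1, nL + nR)` over suprathreshold cluster
  voxels per hemisphere, with symmetry declared at `AI <= tau`
  (default 0.5). An empty map is symmetric by convention.

## Pattern classification and voting

The rater is a fixed decision list over composite involvement flags
(occipital; temporo-parietal; posterior cingulate/precuneus; DLPFC;
frontal eye field; premotor/motor) and the asymmetry flag:

1. nothing involved → negative;
2. involvement confined to premotor/motor → PD-like;
3. occipital and temporo-parietal involved → PCA-like if the frontal eye
   field is involved, the map is asymmetric and DLPFC is spared; otherwise
   DLB-like;
4. temporo-parietal and/or posterior cingulate/precuneus without occipital
   → AD-like;
5. otherwise the label of the most-involved composite, ties broken in the
   fixed order DLB > AD > PCA > PD.

This list is the package's single most consequential reconstruction: the
clinical literature describes pattern *prototypes*, not an algorithm. The
order encodes the differential logic (PD is an exclusion pattern; the
PCA/DLB split rests on eye-field foci, asymmetry and DLPFC sparing; AD is
the posterior pattern without occipital involvement).

Human raters vary; four parameterizations of the list
(`min_fraction` 1/2/2/5%, `tau` 0.4/0.5/0.5/0.6) stand in for four experts.
"Supermajority" is read as 3 of 4 (more than a simple majority); without a
quorum the subject is discordant, with the plurality label recorded for
adjudication. Agreement is summarized as mean pairwise Cohen's kappa; pairs
with a vanishing chance-corrected denominator are excluded with a warning.
The synthetic raters are far more concordant than humans — the vote and
kappa machinery is exercised, but human-level disagreement is not modeled.

## Diagnostic statistics

Pairwise cohort evaluation (e.g. DLB vs ADD) excludes subjects carrying a
third pattern label: a DLB patient labeled AD-like is an error *within*
the DLB-vs-ADD differential, but a PD-like label answers a different
question. This exclusion is the only reading arithmetically consistent
with the reference cohort's printed sensitivity of 1 with lower confidence
bound 0.94 (a Clopper-Pearson lower bound of 0.94 at sensitivity 1 implies
n = 64, i.e. the AD-like DLB cases removed). Proportion intervals are
exact Clopper-Pearson in beta-quantile form — Wilson or Wald intervals do
not reproduce the printed bounds. Report values are rounded half-up to two
decimals; two printed interval endpoints sit exactly at a half-unit
rounding boundary of the exact value and are checked at printed precision.

McNemar uses the continuity correction (matching the printed statistic
under the reconstructed discordant counts); Pearson chi-squares are
uncorrected (matching both printed subgroup statistics to three decimals).
Binary subgroup counts are reconstructed from published percentages by
rounding `rate x n` to the nearest integer. Two-sample comparisons default
to Welch's unequal-variance t (the published table does not state the
flavor; a pooled test reaches the same conclusions on the published
summaries). The DeLong test uses the structural-components variance for
paired AUCs, with `Z = 0, p = 1` by convention when the variance
degenerates; its AUCs are checked against explicit pair counting, its
variance against a bootstrap, and its null Z against a standard normal.

## Subtyping

Features are mean *unthresholded* t values over the 14 ROIs — thresholding
would discard the severity gradations that define subtypes. Columns are
standardized before PCA (the reference analysis does not say; standardizing
keeps high-variance occipital ROIs from dominating by construction) and the
smallest number of components reaching 80% cumulative variance is retained,
both configurable.

Ward linkage on supremum-norm (Chebyshev) distances is formally improper —
Ward's criterion is defined for squared Euclidean distances — but the
pairing is applied deliberately, following the convention of the analysis
being reimplemented: the Lance-Williams Ward update
runs on the squared Chebyshev dissimilarities and heights are reported on
the distance scale (the `ward.D2` convention, verified against `hclust` and
an exhaustive agglomerator). Ties break toward the lowest cluster indices,
making the dendrogram deterministic. The number of subgroups is a user
decision (the reference analysis reports k = 2); mean silhouette widths for
k = 2..6 are provided as guidance, not as an automatic selector. Subgroup 1
is the larger one.

## Problem sizes and numerical choices

Volumes are stored as float32 in NIfTI; all statistics are computed in
float64. The validation suite uses: a 112-control database with 200
held-out null controls for the familywise null rate (bound
`0.05 + 3 sqrt(0.05 x 0.95 / 200)`); a 100-subject, 4-pattern cohort
(25 per pattern) for voted-label accuracy, hallmark prevalence and CIS
separation; and 50 replicate cohorts of 20 + 20 DLB subjects with occipital
reductions 0.30 vs 0.15 against a 40-control database for planted-subtype
recovery. These sizes were chosen to make the binomial bounds on each
property informative while keeping a full run desk-scale. The acceptance
script uses a 40-control, 10-per-pattern cohort, 50 null subjects and a
15 + 15 subtype instance under the caller's seed.

## Known limitations

* Bonferroni is conservative relative to random-field or permutation FWE;
  real-data thresholds would differ from SPM's.
* The decision-list rater and the synthetic rater panel cannot reproduce
  human inter-rater variance (published mean kappa 0.80 is not a target).
* Printed image-level clinical results (the 41/31 subgroup split, the CIS
  cutoff 0.82, DeLong Z = 3.01) require the original scans and are out of
  reach by design; only count-derivable statistics are reproduced.
* The asymmetry index and the involvement fraction rule are documented
  reconstructions, calibrated once on the phantom conditions.
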