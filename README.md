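# dlbpet

Single-subject [18F]FDG-PET hypometabolism mapping and diagnostic statistics
for dementia with Lewy bodies (DLB), as an R package plus a numbered analysis
workflow.

## The problem

Glucose hypometabolism patterns on FDG-PET are disease-specific: DLB shows
medial and lateral occipital hypometabolism with temporo-parietal and frontal
involvement, Alzheimer's disease dementia (ADD) a temporo-parietal plus
posterior cingulate/precuneus pattern, the posterior cortical atrophy (PCA)
variant an asymmetric posterior pattern with frontal-eye-field foci, and
Parkinson's disease (PD) at most a limited premotor/motor reduction. Read at
the single-subject level, these maps can support a DLB diagnosis years before
the clinical picture settles. This package implements the full quantitative
chain needed to do that reproducibly:

1. **t-maps** — at every in-mask voxel, ordinary least squares of uptake on
   `[intercept, patient indicator, age]` over a normative control database
   (N = 112 emulated); the negated indicator t is the hypometabolism score,
   with df = (N + 1) − 3. Thresholding is voxel-level FWE by Bonferroni
   (`qt(1 − α/V, df)`, α = 0.05) with a cluster-extent filter (800 mm³,
   i.e. k = 100 voxels of 2 mm edge, rescaled to the current grid).
2. **Hallmarks** — occipital and dorsolateral prefrontal (DLPFC) involvement
   (suprathreshold fraction ≥ 2% of the composite region), the cingulate
   island sign `CIS = mean(PCC) / (mean(precuneus) + mean(cuneus))`, and a
   hemispheric asymmetry index `AI = |nL − nR| / max(1, nL + nR)`.
3. **Pattern classification** — a deterministic decision list standing in for
   expert raters maps each thresholded topography to DLB-like / AD-like /
   PCA-like / PD-like / negative; four rule variants vote with a 3-of-4
   supermajority and inter-rater agreement is summarized by mean pairwise
   Cohen's kappa.
4. **Diagnostic statistics** — sensitivity/specificity/accuracy with exact
   Clopper-Pearson 95% CIs, agreement with the follow-up diagnosis and
   relative gain, McNemar, uncorrected Pearson chi-square, ROC with Youden
   cutoffs, and the paired DeLong test for correlated AUCs.
5. **Metabolic subtyping** — subjects × 14-ROI matrix of mean t values,
   PCA to ≥ 80% cumulative variance, hierarchical clustering with
   supremum-norm (Chebyshev) distances under Ward linkage, and subgroup
   comparisons (chi-square / Welch t).

Clinical scans are not distributable, so the package ships a phantom
generator (`make_atlas()`, `make_cohort()`) producing schematic brain
volumes with the statistical structure the analysis assumes; every stage is
validated end to end on these phantoms.

## Worked example

```r
library(dlbpet)

atlas  <- make_atlas()                       # 40 x 48 x 40 voxels, 4 mm
spec   <- cohort_spec(n_controls = 40, n_patients = c(DLB = 1L), seed = 7)
cohort <- make_cohort(spec, atlas)
pp     <- preprocess_study(cohort$controls, cohort$patients)   # smooth, mask, scale

tm <- fit_subject_tmap(pp$patients[[1]], pp$controls, pp$mask)
tm <- fwe_threshold(tm, 0.05)
cl <- extract_clusters(tm, k = extent_voxels(atlas$voxel_mm))
hp <- hallmark_profile(pp$patients[[1]], cl, atlas)
labs <- vapply(default_raters(), function(r) classify_pattern(hp, r), "")

round(tm$threshold, 2); sum(cl$labels > 0); round(hp$cis, 3); labs[1]
#> 5.54
#> 4964
#> 0.615
#> "DLB_LIKE"
```

The t threshold 5.54 is the Bonferroni quantile for ~41,600 in-mask voxels
at df = 38; the 4,964 suprathreshold voxels cover the injected occipital,
temporo-parietal and frontal reductions; CIS ≈ 0.62 reflects the spared
posterior cingulate between the reduced precuneus and cuneus (a uniform
brain gives 0.5, AD-like maps fall below it); and the rater rule reads the
topography as DLB-like.

## Analysis workflow

`analysis/` contains the numbered drivers, each a thin narrative over the
package functions, writing under `results/`:

    01_simulate_cohort.R       phantom atlas, controls, 4 patient groups (NIfTI + TSV)
    02_single_subject_tmaps.R  preprocessing, GLM t-maps, FWE + extent clusters
    03_hallmarks_patterns.R    hallmark table, rater labels, supermajority vote
    04_diagnostic_performance.R  performance tables, CIS ROC, DeLong, reference stats
    05_subtype_clustering.R    14-ROI features, PCA, Chebyshev-Ward subtypes

Run them in order with `Rscript analysis/01_simulate_cohort.R` etc.

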