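Package: dlbpet
Title: Single-Subject FDG-PET Hypometabolism Mapping and Diagnostics for
    Lewy Body Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise single-subject and group hypometabolism t-maps for
    [18F]FDG-PET against a normative control database, with age as nuisance
    covariate, Bonferroni familywise-error thresholding and cluster-extent
    filtering. Computes discriminative hypometabolism hallmarks for dementia
    with Lewy bodies (occipital involvement, cingulate island sign, DLPFC
    involvement, asymmetry), rule-based disease-pattern classification with
    supermajority rater voting, diagnostic performance statistics (exact
    Clopper-Pearson intervals, ROC/AUC with the paired DeLong test, McNemar,
    Pearson chi-square, Cohen's kappa), and metabolic subtype discovery by
    PCA plus hierarchical clustering with supremum-norm Ward linkage. Ships a
    synthetic brain-phantom generator so the full pipeline is testable
    without clinical scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
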