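#!/usr/bin/env Rscript
## Step 1 -- simulate the study cohort.
##
## Generates the schematic brain atlas, a normative control database and four
## patient groups with disease-specific regional uptake reductions (DLB-like,
## AD-like, PCA-like, PD-like), then writes every uptake volume as NIfTI plus
## the cohort metadata table. Everything downstream reads these files.

suppressMessages(library(dlbpet))

cfg <- validate_config(list(
  phantom = list(n_controls = 30L,
                 n_patients = c(ADD = 8L, PCA = 8L, PD = 8L)),
  seed = 20260930L
))
out <- "results/phantom"
dir.create(file.path(out, "volumes"), recursive = TRUE, showWarnings = FALSE)

atlas <- make_atlas(cfg$grid$shape, cfg$grid$voxel_mm)
spec <- do.call(cohort_spec, c(cfg$phantom, list(seed = cfg$seed)))
cohort <- make_cohort(spec, atlas)

## the DLB group carries two planted metabolic subtypes that differ only in
## occipital severity (30% vs 15% reduction), for the subtype analysis
occ <- c("calcarine", "cuneus", "occipital_sup", "occipital_mid",
         "occipital_inf", "lingual")
dlb_sub <- function(occ_red, seed, tag) {
  sp <- cohort_spec(n_controls = 0L, n_patients = c(DLB = 4L), seed = seed)
  sp$patterns$DLB$rois[occ] <- occ_red
  co <- make_cohort(sp, atlas)
  for (j in seq_along(co$patients)) {
    co$patients[[j]]$id <- sprintf("dlb_%s%02d", tag, j)
  }
  co$metadata$subject_id <- vapply(co$patients, `[[`, "", "id")
  co$metadata$pattern <- paste0("DLB_", tag)
  co
}
severe <- dlb_sub(0.30, cfg$seed + 1L, "severe")
mild <- dlb_sub(0.15, cfg$seed + 2L, "mild")
cohort$patients <- c(severe$patients, mild$patients, cohort$patients)
cohort$metadata <- rbind(cohort$metadata[cohort$metadata$cohort == "control", ],
                         severe$metadata, mild$metadata,
                         cohort$metadata[!cohort$metadata$cohort %in%
                                           c("control"), ])

for (s in c(cohort$controls, cohort$patients)) {
  write_volume(s, file.path(out, "volumes", paste0(s$id, ".nii.gz")))
}
write_tsv(cohort$metadata, file.path(out, "metadata.tsv"))
jsonlite::write_json(cfg, file.path(out, "config.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d controls and %d patients on a %s grid (%g mm voxels)\n",
            length(cohort$controls), length(cohort$patients),
            paste(cfg$grid$shape, collapse = "x"), cfg$grid$voxel_mm))
cat(sprintf("control age %.1f +/- %.1f years; volumes under %s/volumes\n",
            mean(cohort$metadata$age[cohort$metadata$cohort == "control"]),
            sd(cohort$metadata$age[cohort$metadata$cohort == "control"]),
            out))
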