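#!/usr/bin/env Rscript
## Step 4 -- diagnostic performance.
##
## (a) On the phantom cohort: sensitivity/specificity/accuracy of the voted
##     pattern labels for DLB vs AD-like and DLB vs PD-like comparisons, the
##     CIS ROC with its optimal cutoff, and the paired DeLong comparison of
##     the occipital and CIS hallmarks.
## (b) From the tabulated reference cohort counts: the full performance,
##     agreement and subgroup statistics, written as one table.

suppressMessages(library(dlbpet))

out <- "results/diagnostics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
hall <- read_tsv("results/patterns/hallmarks.tsv")
labels <- read_tsv("results/patterns/labels.tsv")

perf_row <- function(name, p) data.frame(
  comparison = name,
  sensitivity = sprintf("%.2f (%.2f-%.2f)", p$rounded["sens"], p$rounded["sens_lo"], p$rounded["sens_hi"]),
  specificity = sprintf("%.2f (%.2f-%.2f)", p$rounded["spec"], p$rounded["spec_lo"], p$rounded["spec_hi"]),
  accuracy = sprintf("%.2f (%.2f-%.2f)", p$rounded["acc"], p$rounded["acc_lo"], p$rounded["acc_hi"]))

## (a) phantom cohort
rows <- list()
for (pair in list(c("DLB", "ADD"), c("DLB", "PD"))) {
  cf <- pairwise_confusion(labels$voted, labels$cohort, pair[1], pair[2])
  rows[[length(rows) + 1]] <- perf_row(paste0("phantom ", pair[1], " vs ", pair[2]),
                                       performance(cf))
}
dlb <- hall$cohort == "DLB"; add <- hall$cohort == "ADD"
roc <- cis_cutoff(hall$cis[dlb], hall$cis[add])
cat(sprintf("phantom CIS ROC: AUC %.3f, optimal cutoff %.3f\n", roc$auc, roc$cutoff))
sub <- dlb | add
dl <- delong_paired(hall$occipital[sub] * 1, hall$cis[sub], dlb[sub])
cat(sprintf("occipital vs CIS (paired DeLong): AUC %.2f vs %.2f, Z = %.2f, p = %.3g\n",
            dl$auc1, dl$auc2, dl$Z, dl$p))

## (b) reference cohort counts
rs <- reproduce_reference_stats()
rows[[length(rows) + 1]] <- perf_row("reference DLB vs ADD", rs$patterns$DLB_vs_ADD)
rows[[length(rows) + 1]] <- perf_row("reference DLB vs PD", rs$patterns$DLB_vs_PD)
for (nm in names(rs$hallmarks$DLB_vs_ADD))
  rows[[length(rows) + 1]] <- perf_row(paste("reference DLB vs ADD:", nm),
                                       rs$hallmarks$DLB_vs_ADD[[nm]])
for (nm in names(rs$hallmarks$DLB_vs_PD))
  rows[[length(rows) + 1]] <- perf_row(paste("reference DLB vs PD:", nm),
                                       rs$hallmarks$DLB_vs_PD[[nm]])
perf_tab <- do.call(rbind, rows)
write_tsv(perf_tab, file.path(out, "performance.tsv"))
print(perf_tab, right = FALSE)

cat(sprintf("\nreference agreement: entry %.1f%%, imaging %.2f%%, relative gain %.1f%% (McNemar chi2 = %.2f, p = %.2g)\n",
            100 * rs$agreement$prop_entry, 100 * rs$agreement$prop_test,
            100 * rs$agreement$relative_gain, rs$mcnemar$statistic, rs$mcnemar$p))
cat(sprintf("reference subgroup chi-squares: VH prevalence %.3f, VH conversion %.3f\n",
            rs$subgroup_chi2$vh_followup$statistic,
            rs$subgroup_chi2$vh_conversion$statistic))
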