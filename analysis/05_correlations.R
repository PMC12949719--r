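#!/usr/bin/env Rscript
# Stage 5: covariate-adjusted correlations within the CD group. (a) ALPS vs
# each tract's FA, adjusting for the demographics plus all three cortisol
# time points, FDR across the 42-tract family; (b) each cortisol time point
# vs ALPS, adjusting for the demographics only.

suppressPackageStartupMessages(library(glymphalps))
dir.create("results", showWarnings = FALSE)
seed <- 1L

gen <- generate_cohort(cohort_config(seed = substream_seed(seed, "cohort-stage")))
cd <- gen$cohort[gen$cohort$group == "CD", ]
covars <- c("age", "sex", "ed", "bmi", "tbv")

atlas <- tract_atlas()
pan <- correlation_panel(cd, "alps", paste0(atlas$tract, "_FA"),
                         c(covars, "cortisol_0000", "cortisol_8am", "cortisol_4pm"))
sig <- pan[pan$significant, c("y", "r", "p_fdr")]
cat("ALPS-tract FA panel, FDR-significant associations:\n")
print(sig, digits = 3, row.names = FALSE)

cort <- do.call(rbind, lapply(c("cortisol_8am", "cortisol_4pm", "cortisol_0000"),
                              function(v) partial_correlation(cd, v, "alps", covars)))
cat("cortisol-ALPS adjusted correlations (CD only):\n")
print(cort[, c("x", "r", "p_raw", "n")], digits = 3, row.names = FALSE)

write.csv(pan, "results/05_alps_tract_correlations.csv", row.names = FALSE)
write.csv(cort, "results/05_cortisol_alps_correlations.csv", row.names = FALSE)
cat("written: results/05_{alps_tract,cortisol_alps}_correlations.csv\n")
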