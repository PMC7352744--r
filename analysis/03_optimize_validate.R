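#!/usr/bin/env Rscript
# Step 3 — formulation optimization and external validation.
#
# Optimizes the formulation by desirability under the shipped goal
# configuration (responses minimized; oil and surfactant maximized,
# lecithin and glycerol targeted) and validates the published equations
# against the eight external formulations by residual standard error.

suppressPackageStartupMessages(library(mixaero))
dir.create("results", showWarnings = FALSE)

models <- dcn_models()
opt <- optimize_formulation(dcn_goal(models), dcn_region())
cat("Optimized formulation (wt%):\n")
print(round(opt$blend, 3))
cat(sprintf("overall desirability %.4f\n", opt$desirability))
cat("predicted responses at the optimum:\n")
print(round(opt$predictions, 2))
utils::write.csv(
  data.frame(component = names(opt$blend), amount_wt = unname(opt$blend)),
  "results/optimum_formulation.csv", row.names = FALSE)

v <- dcn_validation()
tab <- v[, c("formulation", "A", "B", "C", "D", "E")]
tab$ps_dtx <- ifelse(v$drug == "DTX", v$ps_actual, NA)
tab$ps_ccm <- ifelse(v$drug == "CCM", v$ps_actual, NA)
tab$vmd_dtx <- ifelse(v$drug == "DTX", v$vmd_actual, NA)
tab$vmd_ccm <- ifelse(v$drug == "CCM", v$vmd_actual, NA)
rec <- suppressWarnings(validate_formulations(models, tab, rse_bound = 5))
cat("\nExternal validation (published equations):\n")
cat(report_validation(rec, "text"), "\n")
ps <- rec[grepl("^ps", rec$response), ]
vmd <- rec[grepl("^vmd", rec$response), ]
cat(sprintf("max |RSE|: particle size %.2f%%, VMD %.2f%%\n",
            max(ps$abs_rse), max(vmd$abs_rse)))
utils::write.csv(rec, "results/validation_records.csv", row.names = FALSE)
cat("wrote results/optimum_formulation.csv, results/validation_records.csv\n")
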