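#!/usr/bin/env Rscript
# Stage 2: region harmonization and exclusions.
#
# Sums left/right hemispheres, merges caudate nucleus + accumbens into a
# single region (method m5 arrives pre-merged), drops failed segmentations,
# and excludes reference subjects whose volume lies more than 5 population
# SDs from the region mean for ANY method (union rule: one per-region
# subject set shared by all methods). Emits the cleaned table, the
# exclusion report and the mean (SD) volume summary.

suppressPackageStartupMessages(library(normvol))

cohort <- read_cohort_table("results/cohort.csv")
prep <- preprocess_cohort(cohort, threshold = 5, premerged_methods = "m5")

write_cohort_table(prep$table, "results/cohort_preprocessed.csv")
write_exclusion_report(prep$report, "results/exclusions.csv")
write.csv(volume_summary(prep$table), "results/volume_summary.csv",
          row.names = FALSE)

cat(sprintf("preprocessed: %d records kept of %d (after hemisphere merge)\n",
            nrow(prep$table), nrow(cohort) / 2))
cat("included reference subjects per region:\n")
print(prep$report$included_n)
cat("wrote results/cohort_preprocessed.csv, exclusions.csv, volume_summary.csv\n")
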