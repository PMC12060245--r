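#!/usr/bin/env Rscript

# Step 7 — compare SEC22 expression between backgrounds.
#
# RPKM-normalizes the count table (library size = total counted reads per
# sample) and compares SEC22 between S288C and UWOPS87-2421 with a
# two-sided Student's t-test over replicates. The synthetic table plants a
# 1.25-fold UWOPS87-2421 increase, the size of effect a 5' UTR variant can
# produce; the pipeline should read it back as ~+25%.

suppressPackageStartupMessages(library(supscan))

cohort_dir <- "results/cohort"
counts <- read_counts(file.path(cohort_dir, "counts.tsv"))

cmp <- compare_strains(counts, "SEC22", "S288C", "UWOPS87-2421")
write.table(cmp, "results/expression_sec22.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("SEC22: mean RPKM %.1f (S288C) vs %.1f (UWOPS87-2421): %+.1f%% (p = %.2g)",
                cmp$mean_rpkm_a, cmp$mean_rpkm_b, cmp$percent_change,
                cmp$p_value))

# control genes should sit near 0% change
for (g in c("SEC17", "SEC18", "GLN1")) {
  c0 <- compare_strains(counts, g, "S288C", "UWOPS87-2421")
  message(sprintf("%s (no planted effect): %+.1f%% (p = %.2g)", g,
                  c0$percent_change, c0$p_value))
}
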