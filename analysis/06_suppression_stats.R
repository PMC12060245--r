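#!/usr/bin/env Rscript

# Step 6 — quantify suppression strength and its conservation across
# genetic backgrounds.
#
# For every suppressor x background x condition: mean fold increase in
# colony size over the matched control and a one-sided Welch test
# (suppressor > control), Bonferroni-corrected over the whole batch. The
# best condition per suppressor x background feeds the conservation
# matrix. Also runs the Tukey HSD combined-overexpression comparison on
# wild-type-normalized fitness.

suppressPackageStartupMessages(library(supscan))

cohort_dir <- "results/cohort"
colonies <- read.table(file.path(cohort_dir, "colonies.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)

results <- suppression_tests(colonies, alpha = 0.05, min_fold = 1.0)
write.table(results, "results/suppression_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

best <- best_condition(results)
cons <- conservation_matrix(results)
cons_df <- cbind(suppressor = rownames(cons$matrix),
                  as.data.frame(cons$matrix))
write.table(cons_df, "results/conservation_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(cons$summary)
message("non-conserved: ",
        paste(names(cons$conserved)[!cons$conserved], collapse = ", "))
message("fold-change range across best conditions: ",
        sprintf("%.2f-%.2f", min(best$fold_change), max(best$fold_change)))

# combined overexpression: Tukey HSD on wild-type-normalized fitness.
# The colony table holds single-gene conditions; build the combination
# groups from a dedicated simulated experiment at the study's scale.
eff <- expand.grid(background = "S288C",
                    genotype = c("wild-type", "SEC18", "SEC22", "SCT1",
                                 "SEC18+SEC22", "SEC18+SCT1", "SEC18+SEC22+SCT1"),
                    stringsAsFactors = FALSE)
eff$temperature_C <- 33
eff$plasmid <- "CEN"
eff$effect <- c(3.5, 2.0, 1.3, 1.4, 2.4, 2.3, 2.6)
eff$control_mean <- 1000
combo <- simulate_colony_sizes(eff, n_colonies = 200L, seed = 20240606)
combo_norm <- normalize_to_wildtype(combo)
grp <- combo_norm[combo_norm$genotype != "wild-type", ]
tk <- tukey_combinations(grp$normalized_size, grp$genotype)
write.table(tk$pairs, "results/tukey_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("multi-gene combinations significantly above a single gene: ",
        nrow(tk$multi_exceeds_single), " pairwise comparisons")
print(tk$multi_exceeds_single)
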