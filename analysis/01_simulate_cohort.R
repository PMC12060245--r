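#!/usr/bin/env Rscript

# Step 1 — generate the synthetic study cohort.
#
# Emits the complete input bundle the downstream steps consume: a reference
# genome with gene models, one sites-only VCF per parental and suppressor
# strain (27 suppressors, 9 parents), per-strain 30-kb depth tracks at
# ~100x, flow-cytometry ploidy estimates, colony-size tables for the
# conservation experiment and an expression count table, plus the planted
# ground truth as JSON. The genome is emitted at 10% physical scale (with
# windows scaled to match) to keep the demonstration quick; the mutation
# structure, strain layout and effect sizes are the full study design.

suppressPackageStartupMessages(library(supscan))

seed <- 20240601
cohort_dir <- "results/cohort"

message("emitting synthetic cohort to ", cohort_dir, " (seed ", seed, ")")
paths <- emit_cohort(cohort_dir,
                     genome = default_genome(scale = 0.1),
                     depth_spec = depth_track_spec(window_size = 3000L),
                     seed = seed, n_colonies = 100L)

truth <- paths$truth
message(sprintf("cohort: %d suppressor strains, %d parents", nrow(truth$strains),
                length(paths$parents)))
message(sprintf("planted: %d suppressor SNVs (%s), %d aneuploidies (%d full, %d segmental)",
                nrow(truth$snvs),
                paste(names(table(truth$snvs$category)),
                      table(truth$snvs$category), collapse = ", ", sep = ":"),
                nrow(truth$aneuploidies),
                sum(truth$aneuploidies$kind == "full"),
                sum(truth$aneuploidies$kind == "segmental")))
message("class plan: ", paste(names(table(truth$strains$class)),
                              table(truth$strains$class), sep = "=",
                              collapse = ", "))
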