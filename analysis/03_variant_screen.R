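#!/usr/bin/env Rscript

# Step 3 — screen suppressor-strain variants.
#
# Applies the filter chain (Phred quality >= 200, parental subtraction,
# recurrence in > 3 suppressor strains) to every suppressor VCF, annotates
# the survivors' coding consequences, and compares the result with the
# planted truth. Writes the surviving-variant table and the filter ledger.

suppressPackageStartupMessages(library(supscan))

cohort_dir <- "results/cohort"
if (!file.exists(file.path(cohort_dir, "cohort.tsv"))) {
  stop("run analysis/01_simulate_cohort.R first")
}

manifest <- read.table(file.path(cohort_dir, "cohort.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
ref_seqs <- Biostrings::readDNAStringSet(file.path(cohort_dir, "reference.fa"))
names(ref_seqs) <- sub("\\s.*$", "", names(ref_seqs))
genes <- read_gene_models(file.path(cohort_dir, "genes.gff3"))

sup_vcfs <- setNames(file.path(cohort_dir, "vcf", paste0(manifest$strain, ".vcf")),
                      manifest$strain)
parents <- unique(manifest$parent)
par_vcfs <- setNames(file.path(cohort_dir, "vcf", paste0(parents, ".vcf")),
                      parents)

message("screening ", length(sup_vcfs), " suppressor strains against ",
        length(par_vcfs), " parents...")
screen <- run_screen(sup_vcfs, par_vcfs, genes, ref_seqs, filter_config())

write.table(screen$survivors, "results/screen_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(screen$ledger, "results/screen_ledger.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("filter ledger:")
print(screen$ledger)
message("surviving consequence categories:")
print(table(screen$survivors$category))

truth <- jsonlite::read_json(file.path(cohort_dir, "truth.json"),
                             simplifyVector = TRUE)
got <- with(screen$survivors, paste(strain, chrom, pos, ref, alt))
want <- with(truth$snvs, paste(strain, chrom, pos, ref, alt))
message(sprintf("recovery vs planted truth: %d/%d found, %d spurious",
                length(intersect(got, want)), length(want),
                length(setdiff(got, want))))
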