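#!/usr/bin/env Rscript

# Step 5 — classify how suppression arose in each strain, and shortlist
# candidate suppressor genes on aneuploid chromosomes.
#
# The 2x2 of (any nonsynonymous surviving SNP) x (any aneuploidy) gives
# four explanation classes; candidates on called aneuploidies are ranked
# query gene first (dosage suppression by the TS allele itself), then
# known interactors of the query, then the rest.

suppressPackageStartupMessages(library(supscan))

cohort_dir <- "results/cohort"
manifest <- read.table(file.path(cohort_dir, "cohort.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
survivors <- read.table("results/screen_variants.tsv", sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
calls <- read.table("results/aneuploidy_calls.tsv", sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
genes <- read_gene_models(file.path(cohort_dir, "genes.gff3"))
edges <- read.table(file.path(cohort_dir, "edges.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)

explanations <- lapply(manifest$strain, function(strain) {
  classify_strain(survivors[survivors$strain == strain, , drop = FALSE],
                  calls[calls$strain == strain, , drop = FALSE], strain)
})
report <- cohort_report(explanations)
write.table(report$table, "results/strain_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("explanation classes over ", sum(report$counts), " strains:")
print(report$counts)

query_gene_of <- c(`sec17-1` = "SEC17", `tao3-5010` = "TAO3",
                    `gln1-5007` = "GLN1")
shortlists <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  strain <- manifest$strain[i]
  sl <- shortlist_candidates(calls[calls$strain == strain, , drop = FALSE],
                             genes, query_gene_of[[manifest$query[i]]], edges)
  if (nrow(sl)) cbind(strain = strain, sl) else NULL
}))
write.table(shortlists, "results/candidate_shortlist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- shortlists[shortlists$rank == 1, ]
message("strains whose top candidate is the query gene itself (query-dosage suppression): ",
        sum(top$gene_id %in% query_gene_of), " of ", nrow(top),
        " aneuploid strains")
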