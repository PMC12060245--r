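## One-shot orchestration: simulate (optional) -> screen-variants ->
## call-aneuploidy -> classify -> suppression -> expression, with a
## machine-readable summary. Deterministic under a fixed config + seed.

#' Run the whole pipeline on a cohort directory
#'
#' Expects the directory layout written by [emit_cohort()] (reference.fa,
#' genes.gff3, edges.tsv, vcf/, depth/, ploidy.tsv, colonies.tsv,
#' counts.tsv, cohort.tsv). Runs the variant screen, aneuploidy calling,
#' strain classification, suppression statistics and the expression
#' comparison, and writes result tables plus a summary JSON.
#'
#' @param cohort_dir cohort input directory.
#' @param out_dir results directory (default `file.path(cohort_dir,
#'   "results")`).
#' @param config a [filter_config()].
#' @param alpha,min_fold suppression-call thresholds.
#' @param min_windows,full_threshold aneuploidy-caller parameters.
#' @param expression_gene,expression_strains gene and strain pair for the
#'   expression comparison.
#' @return list with `screen`, `karyotypes`, `report`, `suppression`,
#'   `conservation`, `expression`, `summary` (also written as JSON).
#' @export
run_end_to_end <- function(cohort_dir, out_dir = file.path(cohort_dir, "results"),
                           config = filter_config(), alpha = 0.05,
                           min_fold = 1.0, min_windows = 4L,
                           full_threshold = 0.90,
                           expression_gene = "SEC22",
                           expression_strains = c("S288C", "UWOPS87-2421")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_tsv(file.path(cohort_dir, "cohort.tsv"))
  ref_seqs <- Biostrings::readDNAStringSet(file.path(cohort_dir, "reference.fa"))
  names(ref_seqs) <- sub("\\s.*$", "", names(ref_seqs))
  genes <- read_gene_models(file.path(cohort_dir, "genes.gff3"))
  edges <- read_tsv(file.path(cohort_dir, "edges.tsv"))

  sup_vcfs <- setNames(file.path(cohort_dir, "vcf",
                                  paste0(manifest$strain, ".vcf")),
                        manifest$strain)
  parents <- unique(manifest$parent)
  par_vcfs <- setNames(file.path(cohort_dir, "vcf", paste0(parents, ".vcf")),
                        parents)
  matched <- setNames(manifest$parent, manifest$strain)

  screen <- run_screen(sup_vcfs, par_vcfs, genes, ref_seqs, config,
                       matched_parent = matched)
  write_tsv(screen$survivors, file.path(out_dir, "variants.tsv"))

  ploidy <- read_ploidy(file.path(cohort_dir, "ploidy.tsv"))
  karyotypes <- list()
  for (strain in manifest$strain) {
    dc <- ploidy$dna_content[ploidy$strain == strain]
    karyotypes[[strain]] <- call_strain_karyotype(
      file.path(cohort_dir, "depth", paste0(strain, ".bedgraph")),
      dc, strain, min_windows = min_windows, full_threshold = full_threshold)
  }
  calls <- do.call(rbind, lapply(karyotypes, `[[`, "calls"))
  rownames(calls) <- NULL
  write_tsv(calls, file.path(out_dir, "aneuploidy_calls.tsv"))

  qt <- query_table()
  explanations <- lapply(manifest$strain, function(strain) {
    classify_strain(
      screen$survivors[screen$survivors$strain == strain, , drop = FALSE],
      calls[calls$strain == strain, , drop = FALSE], strain)
  })
  report <- cohort_report(explanations)
  write_tsv(report$table, file.path(out_dir, "explanations.tsv"))

  shortlists <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    strain <- manifest$strain[i]
    query_gene <- qt$gene[qt$query == manifest$query[i]]
    sl <- shortlist_candidates(calls[calls$strain == strain, , drop = FALSE],
                               genes, query_gene, edges)
    if (nrow(sl)) cbind(strain = strain, sl) else NULL
  }))
  if (!is.null(shortlists)) {
    write_tsv(shortlists, file.path(out_dir, "shortlist.tsv"))
  }

  colonies <- read_tsv(file.path(cohort_dir, "colonies.tsv"))
  suppression <- suppression_tests(colonies, alpha = alpha, min_fold = min_fold)
  write_tsv(suppression, file.path(out_dir, "suppression.tsv"))
  conservation <- conservation_matrix(suppression)
  cons_df <- as.data.frame(conservation$matrix)
  cons_df <- cbind(suppressor = rownames(cons_df), cons_df)
  write_tsv(cons_df, file.path(out_dir, "conservation.tsv"))

  counts <- read_counts(file.path(cohort_dir, "counts.tsv"))
  expression <- compare_strains(counts, expression_gene,
                                expression_strains[1], expression_strains[2])
  write_tsv(expression, file.path(out_dir, "expression.tsv"))

  summary <- list(
    n_strains = nrow(manifest),
    class_counts = as.list(report$counts),
    n_surviving_variants = nrow(screen$survivors),
    n_aneuploidy_calls = nrow(calls),
    conservation = list(n_conserved = conservation$n_conserved,
                         n_tested = conservation$n_tested),
    expression = list(gene = expression_gene,
                       percent_change = expression$percent_change,
                       p_value = expression$p_value),
    filter_ledger = screen$ledger)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                        auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(screen = screen, karyotypes = karyotypes, report = report,
                 shortlists = shortlists, suppression = suppression,
                 conservation = conservation, expression = expression,
                 summary = summary))
}
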