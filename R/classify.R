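## Combine the variant screen and the karyotype into per-strain explanation
## classes, and shortlist candidate suppressor genes on aneuploid regions.

STRAIN_CLASSES <- c("euploid_snp", "aneuploid_only", "snp_and_aneuploid",
                    "unexplained")

#' Classify how a strain's suppression arose
#'
#' Assigns one of four mutually exclusive classes from the 2x2 of (any
#' nonsynonymous surviving variant) x (any aneuploidy call). Nonsynonymous
#' means missense, nonsense, frameshift or inframe_indel; intergenic and
#' synonymous variants do not count.
#'
#' @param consequence_calls annotated survivors for one strain (may have 0
#'   rows).
#' @param karyotype_calls aneuploidy calls for the same strain (may have 0
#'   rows).
#' @param strain strain label; must match any `strain` column present.
#' @return one-row data.frame `strain`, `class`, `n_nonsynonymous`,
#'   `aneuploid_chromosomes` (comma-separated).
#' @export
classify_strain <- function(consequence_calls, karyotype_calls, strain) {
  for (df in list(consequence_calls, karyotype_calls)) {
    if (nrow(df) && "strain" %in% names(df)) {
      stop_if_not(all(df$strain == strain),
                  "records for strain '%s' passed to classify_strain('%s')",
                  paste(unique(df$strain), collapse = ","), strain)
    }
  }
  n_nonsyn <- sum(consequence_calls$category %in% NONSYNONYMOUS)
  chroms <- unique(karyotype_calls$chrom)
  has_aneu <- length(chroms) > 0L
  class <- if (n_nonsyn >= 1L && !has_aneu) "euploid_snp"
  else if (n_nonsyn == 0L && has_aneu) "aneuploid_only"
  else if (n_nonsyn >= 1L && has_aneu) "snp_and_aneuploid"
  else "unexplained"
  data.frame(strain = strain, class = class, n_nonsynonymous = n_nonsyn,
              aneuploid_chromosomes = paste(sort(chroms), collapse = ","),
              stringsAsFactors = FALSE)
}

#' Shortlist candidate suppressor genes on aneuploid regions
#'
#' Genes overlapping any called aneuploid region are candidates. The query
#' gene (the TS allele's gene) ranks first when it lies on the aneuploidy
#' (dosage suppression by the query allele itself), then genes with a known
#' interaction with the query, then the rest alphabetically.
#'
#' @param karyotype_calls aneuploidy calls (with `chrom`, `start`, `end`).
#' @param gene_models gene-model data.frame.
#' @param query_gene gene id of the TS query gene.
#' @param interaction_edges data.frame `gene_a`, `gene_b` of undirected
#'   interaction evidence (pre-exported; no live database access).
#' @return data.frame `gene_id`, `chromosome`, `on_aneuploidy`,
#'   `interacts_with_query`, `rank`.
#' @export
shortlist_candidates <- function(karyotype_calls, gene_models, query_gene,
                                 interaction_edges = NULL) {
  stop_if_not(nrow(gene_models) > 0L, "empty gene model")
  empty <- data.frame(gene_id = character(0), chromosome = character(0),
                       on_aneuploidy = logical(0),
                       interacts_with_query = logical(0), rank = integer(0),
                       stringsAsFactors = FALSE)
  if (nrow(karyotype_calls) == 0L) return(empty)
  genes <- gene_models[!duplicated(gene_models$gene_id),
                        c("gene_id", "chrom"), drop = FALSE]
  span <- do.call(rbind, lapply(split(gene_models, gene_models$gene_id),
    function(g) data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                            start = min(g$start), end = max(g$end),
                            stringsAsFactors = FALSE)))
  hit <- vapply(seq_len(nrow(span)), function(i) {
    any(karyotype_calls$chrom == span$chrom[i] &
          # calls carry 0-based half-open region bounds; genes 1-based
          karyotype_calls$start < span$end[i] &
          karyotype_calls$end >= span$start[i])
  }, logical(1))
  cand <- span[hit, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  partners <- character(0)
  if (!is.null(interaction_edges) && nrow(interaction_edges)) {
    partners <- unique(c(
      interaction_edges$gene_b[interaction_edges$gene_a == query_gene],
      interaction_edges$gene_a[interaction_edges$gene_b == query_gene]))
  }
  cand$interacts_with_query <- cand$gene_id %in% partners
  tier <- ifelse(cand$gene_id == query_gene, 1L,
                  ifelse(cand$interacts_with_query, 2L, 3L))
  ord <- order(tier, cand$gene_id)
  cand <- cand[ord, , drop = FALSE]
  data.frame(gene_id = cand$gene_id, chromosome = cand$chrom,
              on_aneuploidy = TRUE,
              interacts_with_query = cand$interacts_with_query,
              rank = seq_len(nrow(cand)), stringsAsFactors = FALSE,
              row.names = NULL)
}

#' Summarise explanation classes over a cohort
#'
#' @param explanations list (or rbind-able set) of [classify_strain()] rows.
#' @return list with `table` (per-strain rows, ordered by strain) and
#'   `counts` (named count per class; sums to the cohort size).
#' @export
cohort_report <- function(explanations) {
  tab <- if (is.data.frame(explanations)) explanations
  else do.call(rbind, explanations)
  stop_if_not(nrow(tab) >= 1L, "no strains to report")
  tab <- tab[order(tab$strain), , drop = FALSE]
  rownames(tab) <- NULL
  counts <- table(factor(tab$class, levels = STRAIN_CLASSES))
  list(table = tab, counts = setNames(as.integer(counts), names(counts)))
}
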