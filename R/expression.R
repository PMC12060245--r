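## RPKM normalization of per-gene read counts and between-strain
## comparison of selected genes.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (gene_length/1000) / (total_reads/1e6)`. The per-sample
#' denominator is the total of counted gene reads in that sample.
#'
#' @param raw_count reads assigned to the gene.
#' @param gene_length gene length in bp.
#' @param sample_total_reads total reads in the sample.
#' @return RPKM value(s).
#' @export
rpkm <- function(raw_count, gene_length, sample_total_reads) {
  stop_if_not(all(sample_total_reads > 0), "sample_total_reads must be > 0")
  stop_if_not(all(gene_length > 0), "gene_length must be > 0")
  raw_count / (gene_length / 1000) / (sample_total_reads / 1e6)
}

#' Read a counts table
#'
#' @param path TSV with columns `gene_id`, `strain`, `replicate`,
#'   `raw_count`, `gene_length_bp`.
#' @return data.frame.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "strain", "replicate", "raw_count", "gene_length_bp")
  stop_if_not(all(need %in% names(df)),
              "counts table needs columns %s", paste(need, collapse = ", "))
  stop_if_not(all(df$raw_count >= 0), "negative raw_count")
  stop_if_not(all(df$gene_length_bp > 0), "non-positive gene_length_bp")
  df
}

#' Add per-replicate RPKM to a counts table
#'
#' The library size for each strain x replicate sample is the sum of that
#' sample's counted gene reads.
#'
#' @param counts counts data.frame (see [read_counts()]).
#' @return `counts` with added `rpkm`.
#' @export
add_rpkm <- function(counts) {
  sample_key <- interaction(counts$strain, counts$replicate, drop = TRUE)
  totals <- tapply(counts$raw_count, sample_key, sum)
  counts$rpkm <- rpkm(counts$raw_count, counts$gene_length_bp,
                      as.numeric(totals[sample_key]))
  counts
}

#' Compare a gene's expression between two strains
#'
#' Mean RPKM per strain over replicates, percent change of strain_b
#' relative to strain_a, and a two-sided equal-variance Student's t-test on
#' the replicate RPKM values.
#'
#' @param counts counts data.frame (RPKM added if absent).
#' @param gene_id gene to compare.
#' @param strain_a,strain_b the two strains (`percent_change` is b vs a).
#' @return one-row data.frame `gene_id`, `mean_rpkm_a`, `mean_rpkm_b`,
#'   `percent_change`, `p_value`, `n_a`, `n_b`.
#' @export
compare_strains <- function(counts, gene_id, strain_a, strain_b) {
  if (!"rpkm" %in% names(counts)) counts <- add_rpkm(counts)
  g <- counts[counts$gene_id == gene_id, , drop = FALSE]
  stop_if_not(nrow(g) > 0L, "gene '%s' not in counts table", gene_id)
  a <- g$rpkm[g$strain == strain_a]
  b <- g$rpkm[g$strain == strain_b]
  stop_if_not(length(a) >= 2L && length(b) >= 2L,
              "need >= 2 replicates per strain for '%s'", gene_id)
  mean_a <- mean(a); mean_b <- mean(b)
  stop_if_not(mean_a > 0, "percent change undefined: mean RPKM of %s is 0",
              strain_a)
  # degenerate replicate sets (zero variance in both strains) have no
  # Student statistic; report the limiting p
  p <- if (var(a) == 0 && var(b) == 0) {
    if (mean_a == mean_b) 1 else 0
  } else t.test(a, b, var.equal = TRUE)$p.value
  data.frame(gene_id = gene_id, mean_rpkm_a = mean_a, mean_rpkm_b = mean_b,
              percent_change = 100 * (mean_b - mean_a) / mean_a,
              p_value = p, n_a = length(a), n_b = length(b),
              stringsAsFactors = FALSE)
}
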