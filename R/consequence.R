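## Minimal coding-consequence annotation: single transcript per gene,
## categories {intergenic, synonymous, missense, nonsense, frameshift,
## inframe_indel}. Positions not overlapping any CDS are intergenic
## (UTR/intron subcategories are out of scope).

CONSEQUENCE_LEVELS <- c("intergenic", "synonymous", "missense", "nonsense",
                        "frameshift", "inframe_indel")
NONSYNONYMOUS <- c("missense", "nonsense", "frameshift", "inframe_indel")

## CDS bookkeeping for one gene: genomic position of every coding base in
## transcription order, plus the coding sequence itself.
gene_cds <- function(gene_rows, ref_seqs) {
  g <- gene_rows[order(gene_rows$exon_rank), , drop = FALSE]
  minus <- g$strand[1] == "-"
  pos <- unlist(lapply(seq_len(nrow(g)), function(j) {
    p <- seq.int(g$start[j], g$end[j])
    if (minus) rev(p) else p
  }))
  chrom <- g$chrom[1]
  bases <- strsplit(as.character(Biostrings::subseq(
    rep(ref_seqs[chrom], nrow(g)), start = g$start, end = g$end)), "")
  cds <- unlist(lapply(seq_len(nrow(g)), function(j) {
    b <- bases[[j]]
    if (minus) rev(chartr("ACGT", "TGCA", b)) else b
  }))
  list(chrom = chrom, strand = g$strand[1], pos = pos, cds = cds)
}

translate_cds <- function(cds_chars) {
  n <- length(cds_chars) - length(cds_chars) %% 3L
  if (n < 3L) return("")
  codons <- vapply(seq(1L, n, by = 3L), function(i) {
    paste(cds_chars[i:(i + 2L)], collapse = "")
  }, character(1))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Annotate variant consequences against gene models
#'
#' Classifies each variant as intergenic, synonymous, missense, nonsense,
#' frameshift or inframe_indel against single-transcript gene models. SNVs
#' inside a CDS are classified by translating the affected codon (standard
#' nuclear code, strand-aware); indels overlapping a CDS are classified by
#' the length difference modulo 3. The reference allele must match the
#' reference sequence on the + strand.
#'
#' @param records variant data.frame (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param gene_models gene-model data.frame (see [genome_model()]).
#' @param ref_seqs named [Biostrings::DNAStringSet] of chromosome sequences.
#' @return `records` with added columns `gene_id` (NA when intergenic),
#'   `category` and `protein_change` (`"W12*"` style, NA unless an SNV in a
#'   CDS).
#' @export
annotate_consequence <- function(records, gene_models, ref_seqs) {
  n <- nrow(records)
  gene_id <- rep(NA_character_, n)
  category <- rep("intergenic", n)
  protein_change <- rep(NA_character_, n)
  if (n == 0L) {
    return(cbind(records, data.frame(gene_id = gene_id, category = category,
                                      protein_change = protein_change)))
  }
  # reference concordance check (on the + strand, as VCF records are)
  for (i in seq_len(n)) {
    chrom <- records$chrom[i]
    stop_if_not(chrom %in% names(ref_seqs),
                "variant %s:%d on unknown chromosome", chrom, records$pos[i])
    ref_here <- as.character(Biostrings::subseq(
      ref_seqs[[chrom]], records$pos[i],
      records$pos[i] + nchar(records$ref[i]) - 1L))
    stop_if_not(identical(ref_here, records$ref[i]),
                "reference mismatch at %s:%d (VCF ref '%s', reference '%s')",
                chrom, records$pos[i], records$ref[i], ref_here)
  }
  # cache per-gene CDS maps
  ids <- unique(gene_models$gene_id)
  cds_map <- lapply(ids, function(gid) {
    gene_cds(gene_models[gene_models$gene_id == gid, , drop = FALSE], ref_seqs)
  })
  names(cds_map) <- ids

  for (i in seq_len(n)) {
    ref <- records$ref[i]; alt <- records$alt[i]
    pos <- records$pos[i]; chrom <- records$chrom[i]
    span <- seq.int(pos, pos + nchar(ref) - 1L)
    hit <- NULL
    for (gid in ids) {
      cm <- cds_map[[gid]]
      if (cm$chrom == chrom && any(span %in% cm$pos)) { hit <- gid; break }
    }
    if (is.null(hit)) next
    gene_id[i] <- hit
    cm <- cds_map[[hit]]
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      cds_idx <- match(pos, cm$pos)
      codon_i <- (cds_idx - 1L) %/% 3L + 1L
      within <- (cds_idx - 1L) %% 3L + 1L
      codon <- cm$cds[(codon_i - 1L) * 3L + 1:3]
      alt_base <- if (cm$strand == "-") chartr("ACGT", "TGCA", alt) else alt
      codon_alt <- codon
      codon_alt[within] <- alt_base
      aa_ref <- Biostrings::GENETIC_CODE[[paste(codon, collapse = "")]]
      aa_alt <- Biostrings::GENETIC_CODE[[paste(codon_alt, collapse = "")]]
      n_codons <- length(cm$cds) %/% 3L
      if (aa_alt == aa_ref) {
        category[i] <- "synonymous"
      } else if (aa_alt == "*" && codon_i < n_codons) {
        category[i] <- "nonsense"
      } else if (aa_ref == "*" && aa_alt != "*") {
        category[i] <- "missense"  # stop-loss folded into missense (readthrough)
      } else {
        category[i] <- "missense"
      }
      protein_change[i] <- paste0(aa_ref, codon_i, aa_alt)
    } else {
      # indel: classify by the CDS-overlapping length change mod 3
      category[i] <- if (abs(nchar(alt) - nchar(ref)) %% 3L != 0L)
        "frameshift" else "inframe_indel"
    }
  }
  out <- cbind(records,
               data.frame(gene_id = gene_id, category = category,
                           protein_change = protein_change,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Count variants per consequence category
#'
#' @param annotated output of [annotate_consequence()].
#' @param by optional grouping column (e.g. `"strain"`).
#' @return data.frame of counts per category (per group when `by` given).
#' @export
consequence_summary <- function(annotated, by = NULL) {
  f <- factor(annotated$category, levels = CONSEQUENCE_LEVELS)
  if (is.null(by)) {
    as.data.frame(table(category = f), responseName = "n")
  } else {
    as.data.frame(table(group = annotated[[by]], category = f),
                  responseName = "n")
  }
}
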