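## Genome model: chromosome table + single-transcript gene models + the
## genome-wide genetic map length used by the meiosis simulator.

#' Construct a genome model
#'
#' A genome model bundles the chromosome coordinate frame, a set of
#' single-transcript gene models and the genome-wide genetic map length.
#' All downstream modules (variant annotation, depth windowing, the
#' backcross simulator) work against this object.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param genes data.frame of CDS intervals with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (1-based inclusive) and
#'   `exon_rank` (order of the interval in transcription direction).
#'   Several rows per gene describe a spliced CDS; the summed length of a
#'   gene's intervals must be divisible by 3.
#' @param map_cM genome-wide genetic map length in centimorgans. The default
#'   4400 cM matches the standard budding-yeast map; per-chromosome genetic
#'   length is apportioned by physical length.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes = empty_gene_models(), map_cM = 4400) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  stop_if_not(all(chromosomes$length > 0), "chromosome lengths must be > 0")
  stop_if_not(!anyDuplicated(chromosomes$name), "chromosome names must be unique")
  genes <- validate_gene_models(genes, chromosomes)
  stop_if_not(map_cM > 0, "map_cM must be positive")
  structure(list(chromosomes = chromosomes[, c("name", "length")],
                 genes = genes, map_cM = map_cM),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %s bp, %d genes, %.0f cM\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ","),
              length(unique(x$genes$gene_id)), x$map_cM))
  invisible(x)
}

empty_gene_models <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
              start = integer(), end = integer(), exon_rank = integer(),
              stringsAsFactors = FALSE)
}

validate_gene_models <- function(genes, chromosomes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "start", "end")
  stop_if_not(all(need %in% names(genes)), "gene models need columns %s",
              paste(need, collapse = ", "))
  if (!"exon_rank" %in% names(genes)) genes$exon_rank <- 1L
  if (nrow(genes) == 0L) return(genes)
  stop_if_not(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  stop_if_not(all(genes$end >= genes$start), "gene interval end < start")
  chr_len <- setNames(chromosomes$length, chromosomes$name)
  stop_if_not(all(genes$chrom %in% names(chr_len)), "gene on unknown chromosome")
  stop_if_not(all(genes$start >= 1 & genes$end <= chr_len[genes$chrom]),
              "gene interval outside its chromosome")
  cds_len <- tapply(genes$end - genes$start + 1L, genes$gene_id, sum)
  stop_if_not(all(cds_len %% 3L == 0L), "total CDS length must be divisible by 3")
  genes <- genes[order(genes$gene_id, genes$exon_rank), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

## Physical chromosome lengths of the 16 S. cerevisiae nuclear chromosomes
## (reference assembly scale); the synthetic coordinate frame mirrors them.
yeast_chrom_lengths <- function() {
  c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
    chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
    chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
    chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)
}

## Named genes the cohort emulates, placed at fixed relative positions so
## the layout survives genome rescaling. Positions are synthetic; only the
## chromosome assignments mirror the biology (SEC17/SEC18/SCT1 on chrII,
## SEC22 on chrXII, TAO3/SIM1 on chrIX, GLN1 on chrXVI, ...).
named_gene_layout <- function() {
  data.frame(
    gene_id = c("SEC17", "SEC18", "SCT1", "SEC22", "TAO3", "SIM1",
                "GLN1", "LUG1", "CWP2", "PMR1", "SSD1"),
    chrom = c("chrII", "chrII", "chrII", "chrXII", "chrIX", "chrIX",
               "chrXVI", "chrXIV", "chrX", "chrVII", "chrIV"),
    rel_pos = c(0.35, 0.55, 0.75, 0.40, 0.45, 0.65,
                 0.50, 0.30, 0.60, 0.40, 0.55),
    strand = c("+", "-", "+", "+", "+", "-", "+", "+", "-", "+", "-"),
    stringsAsFactors = FALSE)
}

#' Default synthetic yeast genome model
#'
#' Sixteen chromosomes at (optionally scaled) budding-yeast physical
#' lengths, a 4400 cM genome-wide map, and single-exon gene models: the
#' named genes of the screen (SEC17, SEC18, SCT1 on chrII; SEC22 on chrXII;
#' TAO3, SIM1 on chrIX; GLN1 on chrXVI; and others) plus two anonymous
#' filler genes per chromosome. CDS lengths default to 900 bp.
#'
#' @param scale multiplier on physical chromosome lengths (genetic map
#'   length is a property of the design and is not scaled).
#' @param cds_len CDS length in bp per gene (divisible by 3).
#' @return A [genome_model()].
#' @export
default_genome <- function(scale = 1, cds_len = 900L) {
  stopifnot(scale > 0, cds_len %% 3L == 0L)
  len <- pmax(round(yeast_chrom_lengths() * scale), 3L * cds_len)
  chromosomes <- data.frame(name = names(len), length = as.integer(unname(len)),
                             stringsAsFactors = FALSE)
  named <- named_gene_layout()
  filler <- do.call(rbind, lapply(chromosomes$name, function(ch) {
    data.frame(gene_id = paste0("Y", sub("^chr", "", ch), c("L001", "R001")),
                chrom = ch, rel_pos = c(0.12, 0.85),
                strand = c("+", "-"), stringsAsFactors = FALSE)
  }))
  layout <- rbind(named, filler)
  chr_len <- setNames(chromosomes$length, chromosomes$name)
  start <- pmax(1L, pmin(as.integer(round(layout$rel_pos * chr_len[layout$chrom])),
                          as.integer(chr_len[layout$chrom]) - cds_len))
  genes <- data.frame(gene_id = layout$gene_id, chrom = layout$chrom,
                       strand = layout$strand, start = start,
                       end = start + cds_len - 1L, exon_rank = 1L,
                       stringsAsFactors = FALSE)
  genome_model(chromosomes, genes, map_cM = 4400)
}

## Genetic length (cM) per chromosome: genome map apportioned by physical share.
chrom_cM <- function(genome) {
  len <- genome$chromosomes$length
  setNames(genome$map_cM * len / sum(len), genome$chromosomes$name)
}

#' Synthesize a reference sequence for a genome model
#'
#' Random nucleotide sequence per chromosome with valid open reading frames
#' (ATG ... sense codons ... TAA, reverse-complemented on minus-strand
#' genes) embedded at every gene model. Deterministic under `seed`.
#'
#' @param genome a [genome_model()].
#' @param seed integer seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
synth_reference <- function(genome, seed = 1) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
      n <- genome$chromosomes$length[i]
      paste(sample(bases, n, replace = TRUE), collapse = "")
    })
    names(seqs) <- genome$chromosomes$name
    # overwrite gene footprints with ORFs (single-exon assumption for the
    # synthetic genome; the annotator itself handles multi-exon models)
    for (gid in unique(genome$genes$gene_id)) {
      g <- genome$genes[genome$genes$gene_id == gid, , drop = FALSE]
      total <- sum(g$end - g$start + 1L)
      orf <- random_orf(total)
      if (g$strand[1] == "-") orf <- revcomp(orf)
      # lay the (strand-adjusted) ORF across the intervals in genomic order
      g <- g[order(g$start), , drop = FALSE]
      off <- 0L
      for (j in seq_len(nrow(g))) {
        w <- g$end[j] - g$start[j] + 1L
        piece <- substr(orf, off + 1L, off + w)
        s <- seqs[[g$chrom[j]]]
        substr(s, g$start[j], g$end[j]) <- piece
        seqs[[g$chrom[j]]] <- s
        off <- off + w
      }
    }
    Biostrings::DNAStringSet(unlist(seqs))
  })
}

## A random ORF of n bases (n divisible by 3): ATG, sense codons, TAA.
random_orf <- function(n) {
  stopifnot(n %% 3L == 0L, n >= 9L)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*" & codons != "ATG"]
  body <- sample(sense, n / 3L - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read gene models from a GFF3 file
#'
#' Extracts CDS features and assembles single-transcript gene models keyed
#' by the `Parent` (or `ID`) attribute.
#'
#' @param path GFF3 file.
#' @param chromosomes optional chromosome table for validation.
#' @return Gene-model data.frame as used by [genome_model()].
#' @export
read_gene_models <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) return(empty_gene_models())
  parent <- sapply(seq_along(cds), function(i) {
    p <- cds$Parent[[i]]
    if (length(p)) as.character(p[1]) else as.character(cds$ID[i])
  })
  gene_id <- sub("^(transcript|mRNA)[:_-]", "", parent)
  df <- data.frame(gene_id = gene_id,
                    chrom = as.character(GenomicRanges::seqnames(cds)),
                    strand = as.character(GenomicRanges::strand(cds)),
                    start = GenomicRanges::start(cds),
                    end = GenomicRanges::end(cds),
                    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rank <- ave(df$start, df$gene_id, FUN = seq_along)
  df$exon_rank <- ifelse(df$strand == "-",
                          ave(df$start, df$gene_id, FUN = function(x) rev(seq_along(x))),
                          rank)
  df$exon_rank <- as.integer(df$exon_rank)
  if (!is.null(chromosomes)) df <- validate_gene_models(df, chromosomes)
  df[order(df$gene_id, df$exon_rank), , drop = FALSE]
}

## Minimal GFF3 writer for the synthetic cohort (gene + mRNA + CDS rows).
write_gene_models_gff3 <- function(genes, chromosomes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(chromosomes))) {
    writeLines(sprintf("##sequence-region %s 1 %d",
                        chromosomes$name[i], chromosomes$length[i]), con)
  }
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    gs <- min(g$start); ge <- max(g$end); st <- g$strand[1]; ch <- g$chrom[1]
    writeLines(sprintf("%s\tsupscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        ch, gs, ge, st, gid), con)
    writeLines(sprintf("%s\tsupscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=mRNA_%s;Parent=%s",
                        ch, gs, ge, st, gid, gid), con)
    g <- g[order(g$start), , drop = FALSE]
    for (j in seq_len(nrow(g))) {
      writeLines(sprintf("%s\tsupscan\tCDS\t%d\t%d\t.\t%s\t0\tID=CDS_%s.%d;Parent=%s",
                          ch, g$start[j], g$end[j], st, gid, j, gid), con)
    }
  }
  invisible(path)
}
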