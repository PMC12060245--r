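# Independent reference computations the implementation is tested against.
# These are deliberately written from first principles (textbook formulas,
# explicit set algebra, full mutant translation) and share no code with the
# package internals beyond the variant-identity convention.

# Welch's unequal-variance t from the textbook formulas, one-sided
# (x greater), Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = pt(t, df, lower.tail = FALSE))
}

# Brute-force set-algebra oracle for the filter chain: explicit set
# comprehension over the quality / parental / recurrence rules, applied to
# in-memory record sets. Returns surviving (strain, chrom, pos, ref, alt).
screen_oracle <- function(sup_sets, par_sets, min_quality = 200,
                          max_recurrence = 3) {
  vid <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  q <- lapply(sup_sets, function(df) {
    df[!is.na(df$qual) & df$qual >= min_quality, , drop = FALSE]
  })
  parental_ids <- unique(unlist(lapply(par_sets, vid)))
  p <- lapply(q, function(df) df[!(vid(df) %in% parental_ids), , drop = FALSE])
  all <- do.call(rbind, p)
  if (is.null(all) || nrow(all) == 0L) return(all)
  counts <- tapply(all$strain, vid(all), function(s) length(unique(s)))
  recurrent <- names(counts)[counts > max_recurrence]
  out <- all[!(vid(all) %in% recurrent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Consequence oracle: apply the SNV to the chromosome sequence, rebuild and
# translate the FULL mutant CDS, and classify by comparing the two protein
# sequences. Intergenic when the position lies in no CDS interval. Pure
# string operations (only the published codon table is shared with the
# implementation).
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

consequence_oracle <- function(chrom, pos, ref, alt, genes, ref_seqs) {
  hit <- NULL
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    if (any(g$chrom == chrom & g$start <= pos & g$end >= pos)) { hit <- gid; break }
  }
  if (is.null(hit)) return("intergenic")
  g <- genes[genes$gene_id == hit, , drop = FALSE]
  extract_cds <- function(chr_str) {
    gg <- g[order(g$start), , drop = FALSE]
    cds <- paste(substring(chr_str, gg$start, gg$end), collapse = "")
    if (g$strand[1] == "-") cds <- oracle_revcomp(cds)
    cds
  }
  ref_chr_str <- as.character(ref_seqs[[chrom]])
  stopifnot(substr(ref_chr_str, pos, pos) == ref)
  mut_chr_str <- ref_chr_str
  substr(mut_chr_str, pos, pos) <- alt
  p_ref <- oracle_translate(extract_cds(ref_chr_str))
  p_mut <- oracle_translate(extract_cds(mut_chr_str))
  if (identical(p_ref, p_mut)) return("synonymous")
  stop_ref <- regexpr("*", p_ref, fixed = TRUE)
  stop_mut <- regexpr("*", p_mut, fixed = TRUE)
  if (stop_mut > 0 && (stop_ref < 0 || stop_mut < stop_ref)) return("nonsense")
  "missense"
}

# Toy genome for exhaustive annotation tests: three short genes (one on the
# minus strand, one spliced over two CDS intervals) on two small
# chromosomes, with a randomized intergenic background.
toy_genome <- function(seed = 1) {
  set.seed(seed)
  chromosomes <- data.frame(name = c("tA", "tB"), length = c(260L, 160L))
  genes <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    chrom = c("tA", "tA", "tA", "tB"),
    strand = c("+", "-", "-", "+"),
    start = c(21L, 121L, 161L, 41L),
    end = c(80L, 150L, 184L, 100L),
    exon_rank = c(1L, 2L, 1L, 1L))  # minus strand: rightmost interval first
  genome <- genome_model(chromosomes, genes, map_cM = 100)
  ref <- synth_reference(genome, seed = seed)
  list(genome = genome, ref = ref)
}
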