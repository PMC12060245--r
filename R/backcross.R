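## Backcross introgression simulator.
##
## The breeding design being emulated: a donor strain carrying a
## temperature-sensitive (TS) allele is crossed to a recurrent natural
## parent; each round a haploid meiotic segregant carrying the donor allele
## at the TS locus is selected and crossed back to the recurrent parent.
## After n crosses the expected recurrent-parent genome fraction is
## 1 - 2^-n (98.4% for n = 6), reduced slightly by linkage drag around the
## selected locus.
##
## Ancestry along each chromosome is tracked as blocks (start, end, origin);
## each meiosis draws Poisson(cM/100) crossovers per chromosome, positions
## uniform in physical coordinates (the per-chromosome map is taken as
## uniform), no interference.

#' Define a backcross introgression design
#'
#' @param n_crosses total number of crosses (each followed by meiosis);
#'   the study design uses 6.
#' @param ts_chrom,ts_pos chromosome and position (bp) of the selected
#'   TS locus.
#' @param select_ts if `TRUE`, each round's segregant is required to carry
#'   donor ancestry at the TS locus (selection causes linkage drag).
#' @return A `cross_design` list.
#' @export
cross_design <- function(n_crosses = 6L, ts_chrom = "chrII", ts_pos = 300000,
                         select_ts = TRUE) {
  stop_if_not(n_crosses >= 1L, "n_crosses must be >= 1")
  structure(list(n_crosses = as.integer(n_crosses), ts_chrom = ts_chrom,
                 ts_pos = ts_pos, select_ts = isTRUE(select_ts)),
            class = "cross_design")
}

## blocks: data.frame(start, end, origin) covering [1, L]; origin in
## {"donor", "recurrent"}.
pure_hap <- function(L, origin) {
  data.frame(start = 1, end = L, origin = origin, stringsAsFactors = FALSE)
}

## Gamete from a diploid (hapA, hapB) on one chromosome: Poisson(cM/100)
## crossovers, uniform positions, random starting phase.
gamete_chrom <- function(hapA, hapB, L, cM) {
  n_co <- rpois(1L, cM / 100)
  cuts <- sort(sample.int(L - 1L, min(n_co, L - 1L)))
  bounds <- c(1L, cuts + 1L, L + 1L)
  use_a <- sample.int(2L, 1L) == 1L
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L] - 1L
    src <- if (use_a) hapA else hapB
    use_a <- !use_a
    sel <- src[src$end >= lo & src$start <= hi, , drop = FALSE]
    if (nrow(sel)) {
      sel$start <- pmax(sel$start, lo)
      sel$end <- pmin(sel$end, hi)
      pieces[[i]] <- sel
    }
  }
  merge_blocks(do.call(rbind, pieces))
}

## Blocks tile the chromosome contiguously; collapse consecutive
## same-origin runs.
merge_blocks <- function(blocks) {
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  n <- nrow(blocks)
  if (n <= 1L) { rownames(blocks) <- NULL; return(blocks) }
  r <- rle(blocks$origin)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  data.frame(start = blocks$start[idx_start], end = blocks$end[idx_end],
             origin = r$values, stringsAsFactors = FALSE)
}

origin_at <- function(blocks, pos) {
  blocks$origin[blocks$start <= pos & blocks$end >= pos][1]
}

## One full lineage: donor x recurrent, then repeated backcrosses with
## optional selection at the TS locus. Returns list of per-chromosome
## block data.frames.
simulate_lineage <- function(genome, design) {
  cMs <- chrom_cM(genome)
  chr_len <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  haps <- lapply(genome$chromosomes$name, function(ch) pure_hap(chr_len[[ch]], "donor"))
  names(haps) <- genome$chromosomes$name
  for (round in seq_len(design$n_crosses)) {
    haps <- lapply(genome$chromosomes$name, function(ch) {
      recurrent <- pure_hap(chr_len[[ch]], "recurrent")
      g <- gamete_chrom(haps[[ch]], recurrent, chr_len[[ch]], cMs[[ch]])
      if (design$select_ts && ch == design$ts_chrom) {
        # selection acts only on the TS chromosome; other chromosomes
        # segregate independently, so rejection here is exact
        tries <- 0L
        while (origin_at(g, design$ts_pos) != "donor") {
          tries <- tries + 1L
          if (tries > 10000L) stop("no TS-carrying segregant obtainable")
          g <- gamete_chrom(haps[[ch]], recurrent, chr_len[[ch]], cMs[[ch]])
        }
      }
      g
    })
    names(haps) <- genome$chromosomes$name
  }
  haps
}

#' Simulate a backcross introgression series
#'
#' Runs `n_lineages` independent lineages through the design and summarises
#' the recurrent (natural) parent genome fraction per lineage, together
#' with the no-drag closed-form expectation `1 - 2^-n_crosses`.
#'
#' @param genome a [genome_model()]; chromosome physical lengths and the
#'   genome-wide map length drive the crossover model.
#' @param design a [cross_design()].
#' @param n_lineages number of independent lineages.
#' @param seed integer seed; the series is deterministic under it.
#' @param keep_blocks if `TRUE`, per-lineage ancestry block lists are
#'   returned (memory scales with lineages).
#' @return A list with `per_lineage` (data.frame: lineage,
#'   recurrent_fraction, donor_fraction, ts_is_donor),
#'   `mean_recurrent_fraction`, `expected_no_drag`, and optionally `blocks`.
#' @export
simulate_backcross_series <- function(genome, design = cross_design(),
                                      n_lineages = 100L, seed = 1,
                                      keep_blocks = FALSE) {
  stop_if_not(design$ts_chrom %in% genome$chromosomes$name,
              "ts locus chromosome '%s' not in genome", design$ts_chrom)
  chr_len <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  stop_if_not(design$ts_pos >= 1 && design$ts_pos <= chr_len[[design$ts_chrom]],
              "ts locus outside its chromosome")
  total <- sum(chr_len)
  with_seed(seed, {
    res <- vector("list", n_lineages)
    frac <- numeric(n_lineages)
    ts_donor <- logical(n_lineages)
    for (i in seq_len(n_lineages)) {
      haps <- simulate_lineage(genome, design)
      rec_bp <- sum(vapply(haps, function(b) {
        sum((b$end - b$start + 1)[b$origin == "recurrent"])
      }, numeric(1)))
      frac[i] <- rec_bp / total
      ts_donor[i] <- origin_at(haps[[design$ts_chrom]], design$ts_pos) == "donor"
      if (keep_blocks) res[[i]] <- haps
    }
    out <- list(
      per_lineage = data.frame(lineage = seq_len(n_lineages),
                               recurrent_fraction = frac,
                               donor_fraction = 1 - frac,
                               ts_is_donor = ts_donor),
      mean_recurrent_fraction = mean(frac),
      expected_no_drag = 1 - 2^(-design$n_crosses))
    if (keep_blocks) out$blocks <- res
    out
  })
}

#' Project a variant set onto simulated ancestry blocks
#'
#' Returns the subset of `variants` (positions on the recurrent parent's
#' private haplotype) retained in a lineage: those falling inside blocks of
#' the requested ancestry.
#'
#' @param blocks per-chromosome block list from one lineage
#'   (`simulate_backcross_series(..., keep_blocks = TRUE)$blocks[[i]]`).
#' @param variants data.frame with `chrom`, `pos`.
#' @param origin which ancestry retains the variants (`"recurrent"` for
#'   natural-parent variants measured against the donor-derived reference).
#' @return The retained subset of `variants`.
#' @export
introgressed_variants <- function(blocks, variants, origin = "recurrent") {
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    b <- blocks[[variants$chrom[i]]]
    if (is.null(b)) return(FALSE)
    isTRUE(origin_at(b, variants$pos[i]) == origin)
  }, logical(1))
  variants[keep, , drop = FALSE]
}
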