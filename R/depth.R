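## Aneuploidy calling from windowed read depth, corrected by externally
## measured base ploidy (flow-cytometry DNA content). Windows are 30-kb
## tiles by default; relative depth is normalized to the genome-wide median
## window depth (robust to the aneuploid fraction itself), multiplied by
## the integer base ploidy to give a per-window copy estimate, segmented by
## rounding and run-merging, and segments departing from the base ploidy
## become gain/loss calls (full when they cover >= 90% of the chromosome).

#' Read a windowed depth track
#'
#' Accepts 4-column bedGraph (chrom, start, end, depth; 0-based half-open)
#' or a TSV with a header containing those columns. Mitochondrial contigs
#' (`chrM`, `chrMito`, `MT`) are excluded: calling is restricted to the
#' nuclear genome.
#'
#' @param path depth file.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `mean_depth`.
#' @export
read_depth_track <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom|start|depth", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, quote = "", comment.char = "#")
  if (!has_header) names(df)[1:4] <- c("chrom", "start", "end", "mean_depth")
  names(df)[names(df) == "depth"] <- "mean_depth"
  df <- df[, c("chrom", "start", "end", "mean_depth")]
  df <- df[!df$chrom %in% c("chrM", "chrMito", "MT"), , drop = FALSE]
  stop_if_not(all(df$end > df$start), "depth windows must have end > start")
  stop_if_not(all(df$mean_depth >= 0), "negative depth in %s", path)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Read per-strain ploidy estimates
#'
#' @param path TSV with columns `strain`, `dna_content` (genome equivalents
#'   relative to a haploid control).
#' @return data.frame `strain`, `dna_content`.
#' @export
read_ploidy <- function(path) {
  df <- read_tsv(path)
  stop_if_not(all(c("strain", "dna_content") %in% names(df)),
              "ploidy table needs columns strain, dna_content")
  stop_if_not(all(df$dna_content > 0), "dna_content must be > 0")
  df
}

## Integer base ploidy from flow-cytometry DNA content. The screen treats
## strains as 1n or 2n; clearly fractional content (mosaic) is an error.
base_ploidy_from <- function(dna_content) {
  bp <- round(dna_content)
  stop_if_not(bp >= 1, "dna_content %.2f rounds below 1", dna_content)
  stop_if_not(abs(dna_content - bp) <= 0.25,
              "fractional DNA content %.2f: not a 1n/2n strain", dna_content)
  as.integer(bp)
}

#' Normalize windowed depth to the genome-wide median
#'
#' `relative_depth = mean_depth / median(mean_depth)`, making the track
#' scale-invariant; the median (not mean) is used so the normalization is
#' robust to the aneuploid fraction of the genome.
#'
#' @param windows depth-window data.frame.
#' @return `windows` with added `relative_depth`.
#' @export
normalize_depth <- function(windows) {
  stop_if_not(nrow(windows) >= 1L, "no depth windows")
  med <- median(windows$mean_depth)
  stop_if_not(med > 0, "median window depth is zero")
  windows$relative_depth <- windows$mean_depth / med
  windows
}

#' Ploidy-correct relative depth into copy estimates
#'
#' `copy_estimate = relative_depth * base_ploidy`, where base ploidy is the
#' flow-cytometry DNA content rounded to the nearest integer, so a euploid
#' region of a diploid sits at 2 and of a haploid at 1.
#'
#' @param windows output of [normalize_depth()].
#' @param dna_content DNA content relative to a haploid control.
#' @return `windows` with added `copy_estimate` and attribute
#'   `base_ploidy`.
#' @export
ploidy_correct <- function(windows, dna_content) {
  bp <- base_ploidy_from(dna_content)
  windows$copy_estimate <- windows$relative_depth * bp
  attr(windows, "base_ploidy") <- bp
  windows
}

#' Segment copy estimates into integer copy-number runs
#'
#' Within each chromosome, windows are assigned the integer their copy
#' estimate rounds to; maximal runs of the same integer become segments,
#' and runs shorter than `min_windows` are merged into the longer flanking
#' run (an isolated noisy window cannot create a segment). Each segment's
#' copy number is the rounded median copy estimate of its windows.
#'
#' @param windows output of [ploidy_correct()].
#' @param min_windows minimum run length in windows (default 4, i.e.
#'   120 kb at 30-kb windows).
#' @return data.frame `chrom`, `start`, `end`, `copy_number`,
#'   `relative_depth` (median), `n_windows`.
#' @export
segment_copy_number <- function(windows, min_windows = 4L) {
  out <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$start), , drop = FALSE]
    state <- as.integer(round(w$copy_estimate))
    state <- merge_short_runs(state, min_windows)
    r <- rle(state)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    data.frame(
      chrom = w$chrom[1],
      start = w$start[idx_start],
      end = w$end[idx_end],
      copy_number = vapply(seq_along(idx_start), function(k) {
        as.integer(round(median(w$copy_estimate[idx_start[k]:idx_end[k]])))
      }, integer(1)),
      relative_depth = vapply(seq_along(idx_start), function(k) {
        median(w$relative_depth[idx_start[k]:idx_end[k]])
      }, numeric(1)),
      n_windows = r$lengths,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Merge runs shorter than min_windows into the longer flanking run;
## repeat until stable.
merge_short_runs <- function(state, min_windows) {
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1L) return(state)
    short <- which(r$lengths < min_windows)
    if (length(short) == 0L) return(state)
    # merge the shortest run first for determinism
    i <- short[which.min(r$lengths[short])]
    left_len <- if (i > 1L) r$lengths[i - 1L] else -1L
    right_len <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    target <- if (left_len >= right_len) r$values[i - 1L] else r$values[i + 1L]
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    state[idx_start[i]:idx_end[i]] <- target
  }
}

#' Call aneuploidies from copy-number segments
#'
#' Segments departing from the base ploidy become calls; per chromosome,
#' deviant segments sharing a copy number whose combined extent is at least
#' `full_threshold` of the windowed chromosome length are reported as one
#' `full` chromosome call, otherwise as `segmental` calls.
#'
#' @param segments output of [segment_copy_number()].
#' @param base_ploidy integer base ploidy of the strain.
#' @param full_threshold fraction of the chromosome required for a `full`
#'   call (default 0.90).
#' @param strain strain label attached to the calls.
#' @param noisy_chromosomes chromosomes flagged noisy by [flag_noisy()];
#'   calls confined to them are annotated low-confidence.
#' @return data.frame `strain`, `chrom`, `kind`, `direction`,
#'   `copy_number`, `extent_fraction`, `start`, `end`, `confidence`.
#' @export
call_aneuploidies <- function(segments, base_ploidy, full_threshold = 0.90,
                              strain = NA_character_,
                              noisy_chromosomes = character(0)) {
  empty <- data.frame(strain = character(0), chrom = character(0),
                       kind = character(0), direction = character(0),
                       copy_number = integer(0), extent_fraction = numeric(0),
                       start = numeric(0), end = numeric(0),
                       confidence = character(0), stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  calls <- lapply(split(segments, segments$chrom), function(seg) {
    chrom_len <- sum(seg$end - seg$start)
    dev <- seg[seg$copy_number != base_ploidy, , drop = FALSE]
    if (nrow(dev) == 0L) return(NULL)
    do.call(rbind, lapply(split(dev, dev$copy_number), function(d) {
      extent <- sum(d$end - d$start) / chrom_len
      if (extent >= full_threshold) {
        data.frame(strain = strain, chrom = d$chrom[1], kind = "full",
                    direction = if (d$copy_number[1] > base_ploidy) "gain" else "loss",
                    copy_number = d$copy_number[1], extent_fraction = extent,
                    start = min(seg$start), end = max(seg$end),
                    stringsAsFactors = FALSE)
      } else {
        data.frame(strain = strain, chrom = d$chrom, kind = "segmental",
                    direction = ifelse(d$copy_number > base_ploidy, "gain", "loss"),
                    copy_number = d$copy_number,
                    extent_fraction = (d$end - d$start) / chrom_len,
                    start = d$start, end = d$end, stringsAsFactors = FALSE)
      }
    }))
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) return(empty)
  out$confidence <- ifelse(out$chrom %in% noisy_chromosomes, "low", "high")
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Flag chromosomes with unusually dispersed depth
#'
#' Reports per-chromosome dispersion (MAD of relative depth about the
#' chromosome median) and flags chromosomes whose dispersion exceeds
#' `mad_factor` times the genome-wide MAD. In real screens the small
#' chromosomes (I, III, VI) tend to be flagged because their capture during
#' DNA isolation varies between samples.
#'
#' @param windows output of [normalize_depth()].
#' @param mad_factor flagging threshold (default 2).
#' @return data.frame `chrom`, `mad`, `genome_mad`, `flagged`.
#' @export
flag_noisy <- function(windows, mad_factor = 2) {
  genome_mad <- mad(windows$relative_depth)
  per <- vapply(split(windows$relative_depth, windows$chrom), mad, numeric(1))
  data.frame(chrom = names(per), mad = as.numeric(per),
              genome_mad = genome_mad,
              flagged = as.numeric(per) > mad_factor * genome_mad,
              stringsAsFactors = FALSE, row.names = NULL)
}

#' Call a strain's karyotype from files
#'
#' Convenience wrapper: read depth track + ploidy, normalize, ploidy-correct,
#' segment, flag noisy chromosomes and call aneuploidies.
#'
#' @param depth_path depth track file.
#' @param dna_content the strain's DNA content (genome equivalents).
#' @param strain strain label.
#' @param min_windows,full_threshold,mad_factor tuning parameters, see
#'   [segment_copy_number()], [call_aneuploidies()], [flag_noisy()].
#' @return list with `calls`, `segments`, `noise`, `base_ploidy`.
#' @export
call_strain_karyotype <- function(depth_path, dna_content, strain,
                                  min_windows = 4L, full_threshold = 0.90,
                                  mad_factor = 2) {
  w <- read_depth_track(depth_path)
  w <- normalize_depth(w)
  w <- ploidy_correct(w, dna_content)
  bp <- attr(w, "base_ploidy")
  noise <- flag_noisy(w, mad_factor)
  seg <- segment_copy_number(w, min_windows)
  calls <- call_aneuploidies(seg, bp, full_threshold, strain = strain,
                             noisy_chromosomes = noise$chrom[noise$flagged])
  list(calls = calls, segments = seg, noise = noise, base_ploidy = bp)
}
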