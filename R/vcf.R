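## VCF I/O for the screen. Reading goes through vcfR; records are held as a
## plain data.frame, one row per ALT allele (multiallelic sites split).
## Writing emits a minimal sites-only VCF v4.2 with deterministic formatting.

#' Read variant records from a VCF file
#'
#' Returns one record per ALT allele; multiallelic sites are split. A
#' missing QUAL (`.`) is carried as `NA` with `qual_missing = TRUE` so the
#' quality filter can count such records separately.
#'
#' @param path VCF v4.x file (sites-only or with samples; only the fixed
#'   columns are consumed).
#' @param strain strain label to attach; defaults to the file name without
#'   extension.
#' @return data.frame with columns `strain`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `qual_missing`.
#' @export
read_vcf <- function(path, strain = NULL) {
  stop_if_not(file.exists(path), "VCF not found: %s", path)
  strain <- strain %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop(sprintf("malformed VCF '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  fx <- vcfR::getFIX(v)
  if (is.null(fx)) return(empty_variants(strain))
  if (!is.matrix(fx)) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) return(empty_variants(strain))
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  alt_list <- strsplit(fx$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep.int(seq_len(nrow(fx)), n_alt)
  qual <- suppressWarnings(as.numeric(fx$QUAL[idx]))
  out <- data.frame(strain = strain,
                     chrom = fx$CHROM[idx],
                     pos = as.integer(fx$POS[idx]),
                     ref = fx$REF[idx],
                     alt = unlist(alt_list),
                     qual = qual,
                     qual_missing = is.na(qual),
                     stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_variants <- function(strain = character(0)) {
  data.frame(strain = character(0), chrom = character(0), pos = integer(0),
              ref = character(0), alt = character(0), qual = numeric(0),
              qual_missing = logical(0), stringsAsFactors = FALSE)
}

#' Write variant records as a sites-only VCF v4.2
#'
#' @param records variant data.frame (`chrom`, `pos`, `ref`, `alt`, `qual`).
#' @param path output path.
#' @param chromosomes optional chromosome table for contig header lines.
#' @param provenance optional named character vector written as
#'   `##key=value` header lines (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, chromosomes = NULL, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=supscan", con)
  for (k in names(provenance)) {
    writeLines(sprintf("##%s=%s", k, provenance[[k]]), con)
  }
  if (!is.null(chromosomes)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                        chromosomes$name, chromosomes$length), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(records)) {
    records <- records[order(records$chrom, records$pos, records$alt), , drop = FALSE]
    qual <- ifelse(is.na(records$qual), ".", fmt_num(records$qual, 1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.",
                        records$chrom, records$pos, records$ref, records$alt,
                        qual), con)
  }
  invisible(path)
}

## Canonical variant identity: quality and strain are not part of it.
variant_id <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}
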