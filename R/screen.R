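## The suppressor-variant filter chain: quality filter, parental
## subtraction, recurrence filter, then consequence annotation. Variants
## surviving all three filters are the candidate de novo suppressor events.

#' Filter chain configuration
#'
#' @param min_quality minimum Phred QUAL retained; records with quality
#'   strictly below are removed (the screen's default is 200).
#' @param max_recurrence a variant identity seen in strictly more than this
#'   many distinct suppressor strains is treated as a systematic artifact
#'   and removed everywhere (default 3).
#' @param parental_scope `"any_parent"` removes a variant present in any
#'   parental set supplied; `"matched_parent"` only consults the strain's
#'   own parent.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_quality = 200, max_recurrence = 3L,
                          parental_scope = c("any_parent", "matched_parent")) {
  stop_if_not(min_quality >= 0, "min_quality must be >= 0")
  stop_if_not(max_recurrence >= 1L, "max_recurrence must be >= 1")
  structure(list(min_quality = min_quality,
                 max_recurrence = as.integer(max_recurrence),
                 parental_scope = match.arg(parental_scope)),
            class = "filter_config")
}

#' Quality filter
#'
#' Keeps records with `qual >= min_quality`; records with missing QUAL are
#' removed and counted separately (conservative). Input order is preserved.
#'
#' @param records variant data.frame.
#' @param config a [filter_config()].
#' @return list with `kept`, `removed`, and `n_quality_missing`.
#' @export
filter_quality <- function(records, config = filter_config()) {
  missing_q <- records$qual_missing %||% is.na(records$qual)
  if (is.null(records$qual_missing)) records$qual_missing <- missing_q
  keep <- !missing_q & records$qual >= config$min_quality
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       n_quality_missing = sum(missing_q))
}

#' Parental subtraction
#'
#' Removes suppressor records whose identity (chromosome, position, ref,
#' alt) occurs in the parental scope. With `parental_scope = "any_parent"`
#' every supplied parental set is consulted; with `"matched_parent"` only
#' the set named like `matched_parent[strain]`.
#'
#' @param records suppressor variant data.frame.
#' @param parental_sets named list of parental variant data.frames.
#' @param config a [filter_config()].
#' @param matched_parent named character vector strain -> parent name
#'   (required for `"matched_parent"` scope).
#' @return list with `kept` and `removed`.
#' @export
subtract_parental <- function(records, parental_sets, config = filter_config(),
                              matched_parent = NULL) {
  if (length(parental_sets) == 0L) {
    warning("no parental sets supplied; parental subtraction is a pass-through")
    return(list(kept = records, removed = records[0, , drop = FALSE]))
  }
  if (config$parental_scope == "any_parent") {
    parental_ids <- unique(unlist(lapply(parental_sets, variant_id)))
    keep <- !(variant_id(records) %in% parental_ids)
  } else {
    stop_if_not(!is.null(matched_parent),
                "matched_parent mapping required for parental_scope='matched_parent'")
    keep <- vapply(seq_len(nrow(records)), function(i) {
      parent <- matched_parent[[records$strain[i]]]
      stop_if_not(!is.null(parent) && parent %in% names(parental_sets),
                  "no matched parent for strain '%s'", records$strain[i])
      !(variant_id(records[i, , drop = FALSE]) %in%
          variant_id(parental_sets[[parent]]))
    }, logical(1))
    if (nrow(records) == 0L) keep <- logical(0)
  }
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Recurrence filter
#'
#' A variant identity occurring in strictly more than `max_recurrence`
#' distinct suppressor strains is removed from every strain (treated as a
#' systematic calling artifact rather than an independent de novo event).
#'
#' @param records variant data.frame covering the whole cohort (`strain`
#'   column distinguishes strains).
#' @param config a [filter_config()].
#' @return list with `kept`, `removed`, and `recurrence` (data.frame of
#'   identity -> number of strains, for the ledger).
#' @export
filter_recurrent <- function(records, config = filter_config()) {
  if (nrow(records) == 0L) {
    return(list(kept = records, removed = records,
                recurrence = data.frame(id = character(0), n_strains = integer(0))))
  }
  ids <- variant_id(records)
  n_strains <- tapply(records$strain, ids, function(s) length(unique(s)))
  bad <- names(n_strains)[n_strains > config$max_recurrence]
  keep <- !(ids %in% bad)
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       recurrence = data.frame(id = names(n_strains),
                                n_strains = as.integer(n_strains),
                                stringsAsFactors = FALSE, row.names = NULL))
}

#' Run the full variant screen on a cohort
#'
#' Applies quality filter, parental subtraction and the recurrence filter
#' (in that order), then annotates the survivors' coding consequences.
#' Recurrence is counted on post-quality, post-parental records.
#'
#' @param suppressor_vcfs named character vector of suppressor VCF paths
#'   (names are strain labels), or a pre-read named list of record
#'   data.frames.
#' @param parent_vcfs named character vector of parental VCF paths, or a
#'   pre-read named list.
#' @param gene_models gene-model data.frame (or `NULL` to skip annotation).
#' @param ref_seqs reference [Biostrings::DNAStringSet] (or `NULL`).
#' @param config a [filter_config()].
#' @param matched_parent strain -> parent mapping for
#'   `parental_scope = "matched_parent"`.
#' @return list with `survivors` (annotated records, all strains),
#'   `summary` (per-strain per-category counts) and `ledger` (counts in and
#'   removed at each stage).
#' @export
run_screen <- function(suppressor_vcfs, parent_vcfs, gene_models = NULL,
                       ref_seqs = NULL, config = filter_config(),
                       matched_parent = NULL) {
  read_set <- function(x) {
    if (is.character(x)) {
      out <- lapply(names(x), function(nm) read_vcf(x[[nm]], strain = nm))
      names(out) <- names(x)
      out
    } else x
  }
  sup <- read_set(suppressor_vcfs)
  par <- read_set(parent_vcfs)
  stop_if_not(length(sup) >= 1L, "no suppressor strains supplied")
  all_records <- do.call(rbind, c(sup, list(empty_variants())))
  rownames(all_records) <- NULL

  q <- filter_quality(all_records, config)
  p <- subtract_parental(q$kept, par, config, matched_parent = matched_parent)
  r <- filter_recurrent(p$kept, config)
  survivors <- r$kept
  if (!is.null(gene_models) && !is.null(ref_seqs)) {
    survivors <- annotate_consequence(survivors, gene_models, ref_seqs)
    summary <- consequence_summary(survivors, by = "strain")
  } else {
    summary <- as.data.frame(table(strain = survivors$strain), responseName = "n")
  }
  ledger <- data.frame(
    stage = c("input", "quality", "parental", "recurrence", "survivors"),
    n_in = c(nrow(all_records), nrow(all_records), nrow(q$kept), nrow(p$kept),
              nrow(r$kept)),
    n_removed = c(0L, nrow(q$removed), nrow(p$removed), nrow(r$removed), 0L),
    stringsAsFactors = FALSE)
  list(survivors = survivors, summary = summary, ledger = ledger,
       n_quality_missing = q$n_quality_missing, recurrence = r$recurrence)
}
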