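## Colony-size fitness statistics: fold changes, one-sided Welch tests with
## Bonferroni correction, wild-type-normalized fitness with Tukey HSD for
## combined overexpression, and the cross-background conservation matrix.

#' Mean fold change in colony size
#'
#' Ratio of sample means (suppressor over control). Means, not medians,
#' because the reported quantity is the mean fold increase in colony size.
#'
#' @param suppressor_sizes,control_sizes positive numeric vectors.
#' @return unitless ratio.
#' @export
fold_change <- function(suppressor_sizes, control_sizes) {
  stop_if_not(length(suppressor_sizes) >= 1L && length(control_sizes) >= 1L,
              "empty sample")
  stop_if_not(all(suppressor_sizes > 0) && all(control_sizes > 0),
              "colony sizes must be positive")
  mean(suppressor_sizes) / mean(control_sizes)
}

#' One-sided Welch's t-test (suppressor > control)
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom;
#' the alternative is that the suppressor mean exceeds the control mean,
#' so reversed effects report p near 1.
#'
#' @param suppressor_sizes,control_sizes numeric vectors, each n >= 2 with
#'   nonzero variance.
#' @return list `t`, `df`, `p`.
#' @export
welch_one_sided <- function(suppressor_sizes, control_sizes) {
  stop_if_not(length(suppressor_sizes) >= 2L && length(control_sizes) >= 2L,
              "each sample needs n >= 2")
  stop_if_not(var(suppressor_sizes) > 0 || var(control_sizes) > 0,
              "degenerate variance in both samples")
  ht <- t.test(suppressor_sizes, control_sizes, alternative = "greater",
               var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * family_size)`; monotone and order-preserving.
#'
#' @param p_values numeric vector of raw p values.
#' @param family_size number of tests in the family; must be at least the
#'   number of p values supplied.
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  stop_if_not(family_size >= length(p_values),
              "family_size smaller than the number of tests")
  pmin(1, p_values * family_size)
}

#' Normalize colony sizes to the wild-type median of the same background
#'
#' @param colonies colony data.frame with `background`, `genotype`,
#'   `colony_size`.
#' @param wildtype_genotype genotype label of the wild-type rows.
#' @return `colonies` with added `normalized_size`.
#' @export
normalize_to_wildtype <- function(colonies, wildtype_genotype = "wild-type") {
  wt <- colonies[colonies$genotype == wildtype_genotype, , drop = FALSE]
  med <- tapply(wt$colony_size, wt$background, median)
  missing <- setdiff(unique(colonies$background), names(med))
  stop_if_not(length(missing) == 0L,
              "no wild-type sample for background(s): %s",
              paste(missing, collapse = ", "))
  colonies$normalized_size <- colonies$colony_size / as.numeric(med[colonies$background])
  colonies
}

#' Tukey HSD over overexpression-combination groups
#'
#' All pairwise comparisons of group mean normalized fitness, with Tukey's
#' family-wise adjustment; flags which multi-gene groups exceed each
#' single-gene group at the adjusted level.
#'
#' @param normalized_sizes numeric vector of wild-type-normalized sizes.
#' @param groups factor/character of overexpression-combo labels (e.g.
#'   `"SEC18"`, `"SEC18+SEC22"`); a group counts as multi-gene when its
#'   label contains `"+"`.
#' @param alpha significance level for the exceedance report.
#' @return list `pairs` (data.frame `group_a`, `group_b`, `diff`, `p_adj`)
#'   and `multi_exceeds_single` (rows where a multi-gene group beats a
#'   single-gene group with `p_adj < alpha` and a positive difference).
#' @export
tukey_combinations <- function(normalized_sizes, groups, alpha = 0.05) {
  groups <- factor(groups)
  stop_if_not(nlevels(groups) >= 2L, "need >= 2 groups")
  n_per <- table(groups)
  stop_if_not(all(n_per >= 2L), "each group needs n >= 2")
  fit <- aov(normalized_sizes ~ groups)
  tk <- TukeyHSD(fit)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(group_a = vapply(nm, `[`, "", 1L),
                       group_b = vapply(nm, `[`, "", 2L),
                       diff = tk[, "diff"], p_adj = tk[, "p adj"],
                       stringsAsFactors = FALSE, row.names = NULL)
  is_multi <- function(g) grepl("+", g, fixed = TRUE)
  # orient each pair as (multi, single) where applicable
  a_multi <- is_multi(pairs$group_a); b_multi <- is_multi(pairs$group_b)
  sel <- xor(a_multi, b_multi)
  mes <- pairs[sel, , drop = FALSE]
  flip <- is_multi(mes$group_b)
  mes[flip, c("group_a", "group_b")] <- mes[flip, c("group_b", "group_a")]
  mes$diff[flip] <- -mes$diff[flip]
  mes <- mes[mes$diff > 0 & mes$p_adj < alpha, , drop = FALSE]
  names(mes)[1:2] <- c("multi_group", "single_group")
  rownames(mes) <- NULL
  list(pairs = pairs, multi_exceeds_single = mes)
}

#' Suppression tests over a colony table
#'
#' For every suppressor genotype x background x condition (temperature,
#' plasmid) cell with a matching control, computes the mean fold change and
#' the one-sided Welch p (suppressor > control), then applies Bonferroni
#' over the whole batch (the family is all tests in the table, the
#' analysis-batch family rule).
#'
#' @param colonies colony data.frame with columns `background`, `genotype`,
#'   `temperature_C`, `plasmid`, `colony_size`.
#' @param control_genotype genotype label of the no-suppressor control.
#' @param alpha significance level for the `suppressed` flag.
#' @param min_fold minimum fold change additionally required for
#'   `suppressed` (a call needs both signal and significance).
#' @param exclude_genotypes genotypes that are neither controls nor
#'   suppressor candidates (the wild-type reference strain by default).
#' @return data.frame, one row per tested cell: `suppressor`, `background`,
#'   `temperature_C`, `plasmid`, `fold_change`, `t`, `df`, `p_value`,
#'   `p_adjusted`, `suppressed`.
#' @export
suppression_tests <- function(colonies, control_genotype = "control",
                              alpha = 0.05, min_fold = 1.0,
                              exclude_genotypes = "wild-type") {
  need <- c("background", "genotype", "temperature_C", "plasmid", "colony_size")
  stop_if_not(all(need %in% names(colonies)),
              "colony table needs columns %s", paste(need, collapse = ", "))
  colonies <- colonies[!colonies$genotype %in% exclude_genotypes, , drop = FALSE]
  colonies$plasmid[is.na(colonies$plasmid)] <- "none"
  key <- interaction(colonies$background, colonies$temperature_C,
                     colonies$plasmid, drop = TRUE)
  rows <- list()
  for (cell in levels(key)) {
    sub <- colonies[key == cell, , drop = FALSE]
    ctrl <- sub$colony_size[sub$genotype == control_genotype]
    if (length(ctrl) < 2L) next
    for (sup in setdiff(unique(sub$genotype), control_genotype)) {
      sizes <- sub$colony_size[sub$genotype == sup]
      if (length(sizes) < 2L) next
      w <- welch_one_sided(sizes, ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        suppressor = sup, background = sub$background[1],
        temperature_C = sub$temperature_C[1], plasmid = sub$plasmid[1],
        fold_change = fold_change(sizes, ctrl),
        t = w$t, df = w$df, p_value = w$p, stringsAsFactors = FALSE)
    }
  }
  stop_if_not(length(rows) > 0L, "no testable suppressor/control cells")
  out <- do.call(rbind, rows)
  out <- out[order(out$suppressor, out$background, out$temperature_C,
                    out$plasmid), , drop = FALSE]
  out$p_adjusted <- bonferroni(out$p_value, nrow(out))
  out$suppressed <- out$p_adjusted < alpha & out$fold_change > min_fold
  rownames(out) <- NULL
  out
}

#' Pick the best condition per suppressor x background
#'
#' The condition (temperature, plasmid) with the largest fold change is
#' retained; ties break by lowest adjusted p, then by lexicographic
#' condition label.
#'
#' @param results output of [suppression_tests()].
#' @return one row per suppressor x background.
#' @export
best_condition <- function(results) {
  stop_if_not(nrow(results) >= 1L, "no results")
  label <- paste(results$temperature_C, results$plasmid, sep = "/")
  grp <- interaction(results$suppressor, results$background, drop = TRUE)
  picked <- lapply(split(seq_len(nrow(results)), grp), function(idx) {
    r <- results[idx, , drop = FALSE]
    ord <- order(-r$fold_change, r$p_adjusted, label[idx])
    r[ord[1L], , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$suppressor, out$background), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-background conservation matrix
#'
#' Builds the suppressor x background matrix of `suppressed` flags (best
#' condition per cell) and counts suppressors conserved in every tested
#' background.
#'
#' @param results output of [suppression_tests()] (or [best_condition()]).
#' @param require_all_backgrounds if `TRUE` (default), a suppressor missing
#'   a background is counted in the denominator only if tested in at least
#'   one, and untested cells block conservation only when
#'   `untested_blocks = TRUE`.
#' @param untested_blocks whether an untested cell prevents a suppressor
#'   from being called conserved (default `FALSE`: conservation is judged
#'   over tested backgrounds).
#' @return list `matrix` (logical suppressor x background, NA = untested),
#'   `conserved` (named logical per suppressor), `summary` (string
#'   "conserved/tested"), `n_conserved`, `n_tested`.
#' @export
conservation_matrix <- function(results, untested_blocks = FALSE) {
  best <- best_condition(results)
  sups <- sort(unique(best$suppressor))
  bgs <- sort(unique(best$background))
  m <- matrix(NA, nrow = length(sups), ncol = length(bgs),
              dimnames = list(sups, bgs))
  for (i in seq_len(nrow(best))) {
    m[best$suppressor[i], best$background[i]] <- best$suppressed[i]
  }
  conserved <- apply(m, 1L, function(row) {
    if (untested_blocks && anyNA(row)) return(FALSE)
    all(row[!is.na(row)])
  })
  list(matrix = m, conserved = conserved,
       n_conserved = sum(conserved), n_tested = length(sups),
       summary = sprintf("%d of %d suppression interactions conserved",
                          sum(conserved), length(sups)))
}
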