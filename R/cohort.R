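## Synthetic-cohort generator. Emulates the study's breeding design and
## mutation structure: 3 natural isolates diverged 0.40/0.59/0.69% from
## the reference, TS alleles of 3 query genes introgressed by 6 crosses,
## 9 parental strains, 27 suppressor strains with planted suppressor SNVs,
## full and segmental aneuploidies at ~100x depth in 30-kb windows,
## haploid/diploid base ploidies, and colony-size tables with
## background-dependent suppression effects. Every planted event is
## recorded as ground truth keyed to the seed.

#' Strain profile for a natural isolate
#'
#' @param name strain name.
#' @param divergence_rate substitutions per site relative to the reference
#'   (must lie in `[0, 0.05)`).
#' @param base_ploidy 1 or 2.
#' @return A `strain_profile` list.
#' @export
strain_profile <- function(name, divergence_rate, base_ploidy = 1L) {
  stop_if_not(divergence_rate >= 0 && divergence_rate < 0.05,
              "divergence_rate %.4f out of range [0, 0.05)", divergence_rate)
  stop_if_not(base_ploidy %in% c(1L, 2L), "base_ploidy must be 1 or 2")
  structure(list(name = name, divergence_rate = divergence_rate,
                 base_ploidy = as.integer(base_ploidy)),
            class = "strain_profile")
}

## The three natural isolates the cohort emulates and their nucleotide
## divergence from the reference strain.
default_profiles <- function() {
  list(strain_profile("L-1374", 0.0040),
       strain_profile("UWOPS87-2421", 0.0059),
       strain_profile("NCYC110", 0.0069))
}

#' Depth-track specification
#'
#' @param mean_depth target mean window depth for a euploid region at base
#'   ploidy (default ~100x).
#' @param window_size window size in bp (default 30,000).
#' @param dispersion negative-binomial size parameter per window (larger =
#'   tighter); the per-window variance is `mu + mu^2/dispersion`.
#' @param noisy_chromosomes chromosomes with inflated variance, emulating
#'   variable capture of the small chromosomes during DNA isolation.
#' @param noisy_factor dispersion inflation on noisy chromosomes (their NB
#'   size is divided by this; default 3).
#' @return A `depth_track_spec` list.
#' @export
depth_track_spec <- function(mean_depth = 100, window_size = 30000L,
                             dispersion = 300,
                             noisy_chromosomes = c("chrI", "chrIII", "chrVI"),
                             noisy_factor = 3) {
  stop_if_not(mean_depth > 0, "mean_depth must be > 0")
  stop_if_not(window_size > 0, "window_size must be > 0")
  structure(list(mean_depth = mean_depth, window_size = as.integer(window_size),
                 dispersion = dispersion,
                 noisy_chromosomes = noisy_chromosomes,
                 noisy_factor = noisy_factor),
            class = "depth_track_spec")
}

#' Generate the variant set of a natural isolate
#'
#' Draws a binomial number of substitutions (`n ~ Binomial(genome length,
#' divergence_rate)`), places them uniformly without replacement, takes the
#' reference base as REF and a uniformly chosen different base as ALT.
#' Deterministic under `seed`.
#'
#' @param genome a [genome_model()].
#' @param ref_seqs reference [Biostrings::DNAStringSet] (see
#'   [synth_reference()]).
#' @param profile a [strain_profile()].
#' @param seed integer seed.
#' @return variant data.frame (`strain`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `qual_missing`).
#' @export
generate_natural_isolate <- function(genome, ref_seqs, profile, seed = 1) {
  stop_if_not(inherits(profile, "strain_profile"), "profile must be a strain_profile")
  with_seed(seed, {
    lens <- genome$chromosomes$length
    total <- sum(lens)
    n <- rbinom(1L, total, profile$divergence_rate)
    if (n == 0L) return(empty_variants(profile$name))
    flat <- sort(sample.int(total, n))
    cum <- cumsum(lens)
    chrom_i <- findInterval(flat - 1L, c(0, cum[-length(cum)]))
    pos <- flat - c(0, cum)[chrom_i]
    chrom <- genome$chromosomes$name[chrom_i]
    chars <- as.character(ref_seqs)
    ref <- substring(chars[chrom], pos, pos)
    bases <- c("A", "C", "G", "T")
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                   USE.NAMES = FALSE)
    data.frame(strain = profile$name, chrom = chrom, pos = as.integer(pos),
                ref = ref, alt = alt,
                qual = round(runif(n, 200, 2000), 1), qual_missing = FALSE,
                stringsAsFactors = FALSE)
  })
}

## Tile each chromosome into fixed windows (0-based half-open). The final
## partial window is kept if >= half a window, else merged into the
## previous one.
make_windows <- function(genome, window_size) {
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    L <- genome$chromosomes$length[i]
    starts <- seq.int(0L, max(0L, L - 1L), by = window_size)
    ends <- pmin(starts + window_size, L)
    if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)]) < window_size / 2) {
      ends[length(ends) - 1L] <- L
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    data.frame(chrom = genome$chromosomes$name[i], start = starts, end = ends,
                stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Simulate a strain's windowed depth track given its planted aneuploidies.
## The window's read count is negative-binomial around
## mean_depth * copy_number / base_ploidy * window / read_length (so the
## squared CV is ~ 1/reads + 1/dispersion), with inflated dispersion on the
## declared noisy chromosomes; mean depth is reads * read_length / window.
simulate_depth_track <- function(genome, spec, aneuploidies, base_ploidy, seed,
                                 read_length = 100) {
  with_seed(seed, {
    w <- make_windows(genome, spec$window_size)
    cn <- rep(base_ploidy, nrow(w))
    if (!is.null(aneuploidies) && nrow(aneuploidies)) {
      for (i in seq_len(nrow(aneuploidies))) {
        a <- aneuploidies[i, ]
        mid <- (w$start + w$end) / 2
        hit <- w$chrom == a$chrom & mid >= a$start & mid < a$end
        cn[hit] <- a$copy_number
      }
    }
    width <- w$end - w$start
    mu_reads <- spec$mean_depth * (cn / base_ploidy) * width / read_length
    size <- ifelse(w$chrom %in% spec$noisy_chromosomes,
                    spec$dispersion / spec$noisy_factor, spec$dispersion)
    reads <- rnbinom(nrow(w), mu = mu_reads, size = size)
    w$mean_depth <- round(reads * read_length / width, 2)
    w$copy_number_truth <- cn
    w
  })
}

#' Simulate a colony-size table
#'
#' Sizes are drawn log-normally around `control_mean * effect` for each row
#' of the effect table (the log-normal keeps sizes positive; `sdlog`
#' controls the coefficient of variation). The study scale being emulated
#' is ~100 colonies per strain.
#'
#' @param effect_table data.frame with columns `background`, `genotype`,
#'   `temperature_C`, `plasmid`, `effect` (multiplicative colony-size
#'   factor; 1 for controls), `control_mean`.
#' @param n_colonies colonies per strain x condition (default 100).
#' @param sdlog log-scale standard deviation of colony size (default 0.25).
#' @param seed integer seed.
#' @return colony data.frame: `strain`, `background`, `genotype`,
#'   `temperature_C`, `plasmid`, `replicate`, `colony_size`.
#' @export
simulate_colony_sizes <- function(effect_table, n_colonies = 100L,
                                  sdlog = 0.25, seed = 1) {
  stop_if_not(all(effect_table$effect > 0), "effect factors must be > 0")
  stop_if_not(n_colonies >= 2L, "n_colonies must be >= 2")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(effect_table)), function(i) {
      e <- effect_table[i, ]
      mu <- e$control_mean * e$effect
      meanlog <- log(mu) - sdlog^2 / 2  # so E[size] = mu
      sizes <- exp(rnorm(n_colonies, meanlog, sdlog))
      data.frame(strain = paste(e$background, e$genotype, sep = "_"),
                  background = e$background, genotype = e$genotype,
                  temperature_C = e$temperature_C, plasmid = e$plasmid,
                  replicate = rep(1:2, length.out = n_colonies),
                  colony_size = sizes, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default suppression-effect table
#'
#' Eleven suppressor genes tested in four genetic backgrounds at two
#' temperatures, plus per-background controls (the TS strain without the
#' suppressor) and wild-type rows. Effects are > 1 everywhere except
#' SEC22 in UWOPS87-2421 (effect 1: the one non-conserved interaction), so
#' the planted truth is 10 of 11 interactions conserved across all
#' backgrounds.
#'
#' @return effect-table data.frame (see [simulate_colony_sizes()]), with
#'   attribute `conserved_truth`.
#' @export
default_effect_table <- function() {
  backgrounds <- c("S288C", "L-1374", "UWOPS87-2421", "NCYC110")
  suppressors <- c("SEC17", "SEC18", "SCT1", "SEC22", "TAO3", "SIM1",
                    "SSD1", "CWP2", "GLN1", "LUG1", "PMR1")
  control_mean <- c(S288C = 1000, `L-1374` = 950, `UWOPS87-2421` = 1050,
                     NCYC110 = 900)
  # deterministic background-dependent strengths in [1.4, 3.0]
  base_effect <- 1.4 + 1.6 * outer(seq_along(suppressors) - 1,
                                    seq_along(backgrounds) - 1,
                                    function(i, j) ((i * 7 + j * 3) %% 10) / 9)
  rows <- list()
  for (b in seq_along(backgrounds)) {
    for (temp in c(34, 36)) {
      hot <- temp == 36
      # empty-vector controls per plasmid backbone, plus the TS strain and
      # the wild-type strain without plasmid
      for (pl in c("none", "CEN")) {
        rows[[length(rows) + 1L]] <- data.frame(
          background = backgrounds[b], genotype = "control",
          temperature_C = temp, plasmid = pl, effect = 1,
          control_mean = control_mean[[backgrounds[b]]], stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        background = backgrounds[b], genotype = "wild-type",
        temperature_C = temp, plasmid = "none", effect = 3.5,
        control_mean = control_mean[[backgrounds[b]]], stringsAsFactors = FALSE)
      for (s in seq_along(suppressors)) {
        eff <- if (suppressors[s] == "SEC22" && backgrounds[b] == "UWOPS87-2421") 1
        else if (hot) base_effect[s, b] else 1 + 0.6 * (base_effect[s, b] - 1)
        rows[[length(rows) + 1L]] <- data.frame(
          background = backgrounds[b], genotype = suppressors[s],
          temperature_C = temp, plasmid = "CEN", effect = eff,
          control_mean = control_mean[[backgrounds[b]]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  conserved <- setNames(rep(TRUE, length(suppressors)), suppressors)
  conserved["SEC22"] <- FALSE
  attr(out, "conserved_truth") <- conserved
  out
}

#' Simulate an expression count table
#'
#' Poisson counts per gene x strain x replicate around gene-specific base
#' means, with planted per-gene fold changes in the second strain. The
#' default plants a 1.25-fold (+25%) SEC22 increase in UWOPS87-2421
#' relative to S288C, the expression difference the pipeline is meant to
#' recover.
#'
#' @param genome a [genome_model()] (gene lengths are taken from it).
#' @param strains two strain names (fold applies to the second).
#' @param folds named numeric vector gene_id -> fold in `strains[2]`;
#'   unnamed genes get fold 1.
#' @param n_replicates technical replicates per strain (default 3).
#' @param seed integer seed.
#' @return counts data.frame: `gene_id`, `strain`, `replicate`,
#'   `raw_count`, `gene_length_bp`.
#' @export
simulate_expression_counts <- function(genome,
                                       strains = c("S288C", "UWOPS87-2421"),
                                       folds = c(SEC22 = 1.25),
                                       n_replicates = 3L, seed = 1) {
  with_seed(seed, {
    span <- do.call(rbind, lapply(split(genome$genes, genome$genes$gene_id),
      function(g) data.frame(gene_id = g$gene_id[1],
                              gene_length_bp = sum(g$end - g$start + 1L),
                              stringsAsFactors = FALSE)))
    span <- span[order(span$gene_id), , drop = FALSE]
    n_genes <- nrow(span)
    base_mean <- 2000 + 1000 * (seq_len(n_genes) %% 17)
    rows <- list()
    for (s in seq_along(strains)) {
      fold <- rep(1, n_genes)
      named <- intersect(names(folds), span$gene_id)
      if (s == 2L) fold[match(named, span$gene_id)] <- folds[named]
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = span$gene_id, strain = strains[s], replicate = r,
          raw_count = rpois(n_genes, base_mean * fold),
          gene_length_bp = span$gene_length_bp, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## ---------------------------------------------------------------------
## Cohort truth construction

## Queries and where their TS locus lives.
query_table <- function() {
  data.frame(query = c("sec17-1", "tao3-5010", "gln1-5007"),
              gene = c("SEC17", "TAO3", "GLN1"),
              chrom = c("chrII", "chrIX", "chrXVI"),
              stringsAsFactors = FALSE)
}

## Per-strain plan for the default 27-suppressor cohort, mirroring the
## study's structure: 7 euploid strains with 1-4 nonsynonymous SNPs, 16
## aneuploid-only, 3 with both, 1 unexplained; all sec17-1 strains
## duplicate chrII (NCYC110 also chrXII), NCYC110 tao3 strains chrIX,
## L-1374 gln1 strains chrXVI.
cohort_plan <- function() {
  plan <- list()
  add <- function(bg, query, idx, class, n_nonsyn = 0L, aneu = character(0),
                  base_ploidy = 1L, segmental = FALSE) {
    plan[[length(plan) + 1L]] <<- list(
      background = bg, query = query, idx = idx, class = class,
      n_nonsyn = n_nonsyn, aneu_chroms = aneu,
      base_ploidy = base_ploidy, segmental = segmental)
  }
  # sec17-1: 9 aneuploid-only strains, chrII (+chrXII in NCYC110)
  for (i in 1:3) add("L-1374", "sec17-1", i, "aneuploid_only",
                      aneu = "chrII", base_ploidy = if (i == 3) 2L else 1L)
  for (i in 1:3) add("UWOPS87-2421", "sec17-1", i, "aneuploid_only", aneu = "chrII")
  for (i in 1:3) add("NCYC110", "sec17-1", i, "aneuploid_only",
                      aneu = c("chrII", "chrXII"))
  # tao3-5010: L-1374 euploid SNP strains, UWOPS 2 euploid + 1 both,
  # NCYC110 aneuploid chrIX
  nsyn_l <- c(4L, 3L, 2L)
  for (i in 1:3) add("L-1374", "tao3-5010", i, "euploid_snp", n_nonsyn = nsyn_l[i])
  add("UWOPS87-2421", "tao3-5010", 1, "euploid_snp", n_nonsyn = 2L)
  add("UWOPS87-2421", "tao3-5010", 2, "euploid_snp", n_nonsyn = 2L)
  add("UWOPS87-2421", "tao3-5010", 3, "snp_and_aneuploid", n_nonsyn = 1L,
      aneu = "chrIX")
  for (i in 1:3) add("NCYC110", "tao3-5010", i, "aneuploid_only",
                      aneu = "chrIX", base_ploidy = if (i == 2) 2L else 1L)
  # gln1-5007: L-1374 aneuploid chrXVI, UWOPS mixed, NCYC110 SNP strains
  for (i in 1:3) add("L-1374", "gln1-5007", i, "aneuploid_only", aneu = "chrXVI")
  add("UWOPS87-2421", "gln1-5007", 1, "aneuploid_only", aneu = "chrXVI")
  add("UWOPS87-2421", "gln1-5007", 2, "snp_and_aneuploid", n_nonsyn = 1L,
      aneu = "chrXVI", segmental = TRUE)
  add("UWOPS87-2421", "gln1-5007", 3, "snp_and_aneuploid", n_nonsyn = 1L,
      aneu = "chrXVI")
  add("NCYC110", "gln1-5007", 1, "euploid_snp", n_nonsyn = 1L)
  add("NCYC110", "gln1-5007", 2, "euploid_snp", n_nonsyn = 1L)
  add("NCYC110", "gln1-5007", 3, "unexplained")
  plan
}

strain_name <- function(bg, query, idx) {
  sprintf("%s_%s_S%d", gsub("-", "", bg), query, idx)
}
parent_name <- function(bg, query) {
  sprintf("%s_%s_P", gsub("-", "", bg), query)
}

## Plant a coding SNV of the requested category in a gene; returns a
## one-row variant data.frame (without strain/qual). Positions avoid `used`
## identities.
plant_coding_snv <- function(genome, ref_seqs, gene_id, category, used) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  cm <- gene_cds(g, ref_seqs)
  n_codons <- length(cm$cds) %/% 3L
  bases <- c("A", "C", "G", "T")
  for (try in 1:500) {
    codon_i <- sample(2:(n_codons - 1L), 1L)  # leave start & stop codons alone
    within <- sample.int(3L, 1L)
    cds_idx <- (codon_i - 1L) * 3L + within
    codon <- cm$cds[(codon_i - 1L) * 3L + 1:3]
    aa_ref <- Biostrings::GENETIC_CODE[[paste(codon, collapse = "")]]
    for (alt_cds in sample(setdiff(bases, cm$cds[cds_idx]))) {
      codon_alt <- codon
      codon_alt[within] <- alt_cds
      aa_alt <- Biostrings::GENETIC_CODE[[paste(codon_alt, collapse = "")]]
      ok <- switch(category,
                    missense = aa_alt != aa_ref && aa_alt != "*",
                    nonsense = aa_alt == "*",
                    synonymous = aa_alt == aa_ref,
                    FALSE)
      if (!ok) next
      pos <- cm$pos[cds_idx]
      ref <- as.character(Biostrings::subseq(ref_seqs[[cm$chrom]], pos, pos))
      alt <- if (cm$strand == "-") chartr("ACGT", "TGCA", alt_cds) else alt_cds
      id <- paste(cm$chrom, pos, ref, alt, sep = ":")
      if (id %in% used) next
      return(data.frame(chrom = cm$chrom, pos = pos, ref = ref, alt = alt,
                         category = category, gene_id = gene_id,
                         stringsAsFactors = FALSE))
    }
  }
  stop(sprintf("could not plant a %s SNV in %s", category, gene_id))
}

## Plant a 1-bp frameshift insertion inside a gene's CDS.
plant_frameshift <- function(genome, ref_seqs, gene_id, used) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  cm <- gene_cds(g, ref_seqs)
  for (try in 1:100) {
    pos <- sample(cm$pos[4:(length(cm$pos) - 3L)], 1L)
    ref <- as.character(Biostrings::subseq(ref_seqs[[cm$chrom]], pos, pos))
    alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1L))
    id <- paste(cm$chrom, pos, ref, alt, sep = ":")
    if (!(id %in% used)) {
      return(data.frame(chrom = cm$chrom, pos = pos, ref = ref, alt = alt,
                         category = "frameshift", gene_id = gene_id,
                         stringsAsFactors = FALSE))
    }
  }
  stop("could not plant a frameshift")
}

## Plant an intergenic SNV (outside every gene footprint).
plant_intergenic_snv <- function(genome, ref_seqs, used) {
  lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  bases <- c("A", "C", "G", "T")
  for (try in 1:500) {
    chrom <- sample(genome$chromosomes$name, 1L)
    pos <- sample.int(lens[[chrom]], 1L)
    g <- genome$genes
    in_gene <- any(g$chrom == chrom & g$start <= pos & g$end >= pos)
    if (in_gene) next
    ref <- as.character(Biostrings::subseq(ref_seqs[[chrom]], pos, pos))
    alt <- sample(setdiff(bases, ref), 1L)
    id <- paste(chrom, pos, ref, alt, sep = ":")
    if (!(id %in% used)) {
      return(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         category = "intergenic", gene_id = NA_character_,
                         stringsAsFactors = FALSE))
    }
  }
  stop("could not plant an intergenic SNV")
}

## Genes whose loss-of-function or dosage change is a plausible suppressor
## of each query; planted nonsynonymous SNVs go into these.
suppressor_gene_pool <- function() {
  list(`sec17-1` = c("SEC18", "SCT1", "SEC22"),
       `tao3-5010` = c("SSD1", "CWP2", "SIM1"),
       `gln1-5007` = c("LUG1", "PMR1"))
}

#' Build the planted truth for the default cohort
#'
#' Constructs per-strain planted suppressor SNVs (category-controlled:
#' across the cohort, 5 intergenic, 6 nonsense, 2 frameshift and 10
#' missense events for 23 in total), aneuploidies (full chromosome
#' duplications plus one terminal segmental duplication), base ploidies and
#' the strain plan (7/16/3/1 explanation classes over 27 strains).
#'
#' @param genome a [genome_model()].
#' @param ref_seqs reference sequences.
#' @param seed integer seed.
#' @param avoid_ids variant identities (`chrom:pos:ref:alt`) the planted
#'   events must not collide with (the parental variant sets, so no planted
#'   suppressor event is lost to parental subtraction).
#' @return list with `strains` (plan data.frame), `snvs`, `aneuploidies`,
#'   `seed`.
#' @export
cohort_truth <- function(genome, ref_seqs, seed = 1, avoid_ids = character(0)) {
  plan <- cohort_plan()
  qt <- query_table()
  pool <- suppressor_gene_pool()
  with_seed(child_seed(seed, 101), {
    used <- avoid_ids
    snvs <- list()
    aneus <- list()
    strains <- list()
    # cohort-wide category budget for the nonsynonymous events:
    # 6 nonsense + 2 frameshift (premature stop / frameshift class) and 10
    # missense, handed out in a fixed deterministic order
    nonsyn_categories <- c(rep("nonsense", 6L), rep("frameshift", 2L),
                            rep("missense", 10L))
    cat_i <- 0L
    # 5 intergenic events scattered over the first 5 aneuploid-only strains
    intergenic_left <- 5L
    for (p in plan) {
      strain <- strain_name(p$background, p$query, p$idx)
      qrow <- qt[qt$query == p$query, ]
      strains[[length(strains) + 1L]] <- data.frame(
        strain = strain, background = p$background, query = p$query,
        parent = parent_name(p$background, p$query), class = p$class,
        base_ploidy = p$base_ploidy, stringsAsFactors = FALSE)
      if (p$n_nonsyn > 0L) {
        genes <- pool[[p$query]]
        for (k in seq_len(p$n_nonsyn)) {
          cat_i <- cat_i + 1L
          categ <- nonsyn_categories[((cat_i - 1L) %% length(nonsyn_categories)) + 1L]
          gene <- genes[((p$idx + k - 1L) %% length(genes)) + 1L]
          ev <- if (categ == "frameshift") {
            plant_frameshift(genome, ref_seqs, gene, used)
          } else {
            plant_coding_snv(genome, ref_seqs, gene, categ, used)
          }
          ev$strain <- strain
          used <- c(used, paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = ":"))
          snvs[[length(snvs) + 1L]] <- ev
        }
      }
      if (length(p$aneu_chroms)) {
        for (ch in p$aneu_chroms) {
          L <- genome$chromosomes$length[genome$chromosomes$name == ch]
          if (isTRUE(p$segmental) && ch == p$aneu_chroms[1]) {
            start <- round(0.70 * L); end <- L; kind <- "segmental"
          } else {
            start <- 0; end <- L; kind <- "full"
          }
          aneus[[length(aneus) + 1L]] <- data.frame(
            strain = strain, chrom = ch, start = start, end = end,
            copy_number = p$base_ploidy + 1L, kind = kind,
            stringsAsFactors = FALSE)
        }
        if (intergenic_left > 0L && p$class == "aneuploid_only") {
          ev <- plant_intergenic_snv(genome, ref_seqs, used)
          ev$strain <- strain
          used <- c(used, paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = ":"))
          snvs[[length(snvs) + 1L]] <- ev
          intergenic_left <- intergenic_left - 1L
        }
      }
    }
    snv_df <- if (length(snvs)) do.call(rbind, snvs) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), category = character(0),
                  gene_id = character(0), strain = character(0))
    aneu_df <- if (length(aneus)) do.call(rbind, aneus) else
      data.frame(strain = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0),
                  copy_number = integer(0), kind = character(0))
    list(strains = do.call(rbind, strains), snvs = snv_df,
         aneuploidies = aneu_df, seed = seed)
  })
}

#' Emit a complete synthetic cohort to disk
#'
#' Writes reference FASTA, gene models (GFF3), interaction edge list, one
#' sites-only VCF per parental and suppressor strain, per-strain depth
#' tracks (bedGraph), a ploidy table, a colony-size table, an expression
#' count table, the strain manifest and the full planted truth as JSON.
#' Suppressor VCFs contain, besides the planted suppressor SNVs, the three
#' contaminating classes the filter chain must remove: parental-background
#' variants shared with the matched parent, low-quality noise calls
#' (Phred < 200), and recurrent artifact calls present in more than 3
#' suppressor strains. Byte-identical under a fixed seed.
#'
#' @param out_dir output directory (created if needed).
#' @param genome a [genome_model()]; `default_genome()` reproduces the
#'   full-size coordinate frame, `default_genome(scale = ...)` a reduced
#'   one.
#' @param seed integer master seed; recorded in the truth JSON and VCF
#'   headers.
#' @param depth_spec a [depth_track_spec()].
#' @param n_colonies colonies per strain x condition.
#' @param n_noise low-quality noise calls per suppressor strain.
#' @param use_backcross_blocks if `TRUE`, each parent's variant set is the
#'   natural isolate's variants restricted to recurrent-parent ancestry
#'   blocks from a simulated 6-cross introgression (slower, more faithful);
#'   if `FALSE` parents carry the full isolate variant set.
#' @return list of paths plus the `truth` object, invisibly.
#' @export
emit_cohort <- function(out_dir, genome = default_genome(), seed = 1,
                        depth_spec = depth_track_spec(),
                        n_colonies = 100L, n_noise = 30L,
                        use_backcross_blocks = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)
  ref_seqs <- synth_reference(genome, seed = child_seed(seed, 1))
  qt <- query_table()
  profiles <- default_profiles()
  names(profiles) <- vapply(profiles, `[[`, "", "name")

  # reference + annotation
  fasta_path <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(ref_seqs, fasta_path, width = 80L)
  gff_path <- file.path(out_dir, "genes.gff3")
  write_gene_models_gff3(genome$genes, genome$chromosomes, gff_path)
  edges_path <- file.path(out_dir, "edges.tsv")
  write_tsv(default_edges(), edges_path)

  # parental variant sets: one per background x query (9 parents); the
  # backcrossed parent retains the natural isolate's variants inside
  # recurrent-parent ancestry blocks (~98% of them)
  parent_sets <- list()
  for (bg in names(profiles)) {
    iso <- generate_natural_isolate(genome, ref_seqs, profiles[[bg]],
                                     seed = child_seed(seed, 11 + match(bg, names(profiles))))
    for (qi in seq_len(nrow(qt))) {
      pname <- parent_name(bg, qt$query[qi])
      pv <- iso
      if (use_backcross_blocks) {
        design <- cross_design(6L, ts_chrom = qt$chrom[qi],
                               ts_pos = ts_locus_pos(genome, qt$gene[qi]))
        bl <- with_seed(child_seed(seed, 40 + match(bg, names(profiles)) * 3 + qi), {
          simulate_lineage(genome, design)
        })
        pv <- introgressed_variants(bl, iso, origin = "recurrent")
      }
      pv$strain <- pname
      parent_sets[[pname]] <- pv
    }
  }

  # planted events must not collide with any parental identity, or they
  # would be lost to parental subtraction
  truth <- cohort_truth(genome, ref_seqs, seed = seed,
                        avoid_ids = unique(unlist(lapply(parent_sets, variant_id))))

  # per-strain files
  chrom_tab <- genome$chromosomes
  provenance <- c(cohort_seed = as.character(seed))
  vcf_paths <- character(0)
  for (pname in names(parent_sets)) {
    path <- file.path(out_dir, "vcf", paste0(pname, ".vcf"))
    write_vcf(parent_sets[[pname]], path, chrom_tab, provenance)
    vcf_paths[pname] <- path
  }

  sup <- truth$strains
  # recurrent artifacts: identities present in >3 suppressor strains,
  # quality >= 200, absent from every parent
  used_ids <- unique(c(unlist(lapply(parent_sets, variant_id)),
                        paste(truth$snvs$chrom, truth$snvs$pos,
                              truth$snvs$ref, truth$snvs$alt, sep = ":")))
  artifacts <- with_seed(child_seed(seed, 77), {
    a1 <- plant_intergenic_snv(genome, ref_seqs, used_ids)
    a2 <- plant_intergenic_snv(genome, ref_seqs,
                                c(used_ids, paste(a1$chrom, a1$pos, a1$ref, a1$alt, sep = ":")))
    list(list(ev = a1, strains = sup$strain[seq_len(min(5L, nrow(sup)))]),
         list(ev = a2, strains = sup$strain))
  })

  depth_paths <- character(0)
  ploidy_rows <- list()
  for (i in seq_len(nrow(sup))) {
    strain <- sup$strain[i]
    sseed <- child_seed(seed, 1000 + i)
    recs <- parent_sets[[sup$parent[i]]]
    recs$strain <- strain
    planted <- truth$snvs[truth$snvs$strain == strain, , drop = FALSE]
    if (nrow(planted)) {
      planted_v <- with_seed(sseed, data.frame(
        strain = strain, chrom = planted$chrom, pos = as.integer(planted$pos),
        ref = planted$ref, alt = planted$alt,
        qual = round(runif(nrow(planted), 200, 2000), 1),
        qual_missing = FALSE, stringsAsFactors = FALSE))
      recs <- rbind(recs, planted_v)
    }
    # low-quality noise calls, strictly below the Phred 200 boundary
    noise <- with_seed(child_seed(sseed, 2), {
      nz <- lapply(seq_len(n_noise), function(k) {
        plant_intergenic_snv(genome, ref_seqs, used_ids)
      })
      nz <- do.call(rbind, nz)
      data.frame(strain = strain, chrom = nz$chrom, pos = as.integer(nz$pos),
                  ref = nz$ref, alt = nz$alt,
                  qual = round(runif(nrow(nz), 10, 199.9), 1),
                  qual_missing = FALSE, stringsAsFactors = FALSE)
    })
    recs <- rbind(recs, noise)
    for (a in artifacts) {
      if (strain %in% a$strains) {
        recs <- rbind(recs, data.frame(
          strain = strain, chrom = a$ev$chrom, pos = as.integer(a$ev$pos),
          ref = a$ev$ref, alt = a$ev$alt, qual = 500, qual_missing = FALSE,
          stringsAsFactors = FALSE))
      }
    }
    path <- file.path(out_dir, "vcf", paste0(strain, ".vcf"))
    write_vcf(recs, path, chrom_tab, provenance)
    vcf_paths[strain] <- path

    # depth track
    aneu <- truth$aneuploidies[truth$aneuploidies$strain == strain, , drop = FALSE]
    w <- simulate_depth_track(genome, depth_spec, aneu, sup$base_ploidy[i],
                              seed = child_seed(sseed, 3))
    dpath <- file.path(out_dir, "depth", paste0(strain, ".bedgraph"))
    bg <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                      mean_depth = w$mean_depth)
    write.table(bg, dpath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, eol = "\n")
    depth_paths[strain] <- dpath
    # flow-cytometry DNA content with mild measurement noise
    ploidy_rows[[i]] <- data.frame(
      strain = strain,
      dna_content = round(sup$base_ploidy[i] +
                            with_seed(child_seed(sseed, 4), rnorm(1, 0, 0.05)), 2),
      stringsAsFactors = FALSE)
  }
  ploidy_path <- file.path(out_dir, "ploidy.tsv")
  write_tsv(do.call(rbind, ploidy_rows), ploidy_path)

  # colony sizes and expression counts
  colonies <- simulate_colony_sizes(default_effect_table(), n_colonies,
                                    seed = child_seed(seed, 5))
  colony_path <- file.path(out_dir, "colonies.tsv")
  write_tsv(colonies, colony_path)
  counts <- simulate_expression_counts(genome, seed = child_seed(seed, 6))
  counts_path <- file.path(out_dir, "counts.tsv")
  write_tsv(counts, counts_path)

  manifest_path <- file.path(out_dir, "cohort.tsv")
  write_tsv(truth$strains, manifest_path)

  truth_out <- list(seed = seed,
                    strains = truth$strains,
                    snvs = truth$snvs,
                    aneuploidies = truth$aneuploidies,
                    artifact_ids = vapply(artifacts, function(a)
                      paste(a$ev$chrom, a$ev$pos, a$ev$ref, a$ev$alt, sep = ":"), ""),
                    conserved_truth = as.list(attr(default_effect_table(),
                                                    "conserved_truth")),
                    expression_folds = list(SEC22 = 1.25))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth_out, truth_path, auto_unbox = TRUE, digits = NA,
                        pretty = TRUE)

  invisible(list(dir = out_dir, fasta = fasta_path, gff = gff_path,
                 edges = edges_path, vcfs = vcf_paths, depth = depth_paths,
                 ploidy = ploidy_path, colonies = colony_path,
                 counts = counts_path, manifest = manifest_path,
                 truth_json = truth_path, truth = truth_out,
                 parents = names(parent_sets)))
}

## TS locus position: midpoint of the query gene.
ts_locus_pos <- function(genome, gene) {
  g <- genome$genes[genome$genes$gene_id == gene, , drop = FALSE]
  stop_if_not(nrow(g) > 0L, "query gene '%s' not in genome", gene)
  round((min(g$start) + max(g$end)) / 2)
}

#' Default gene-gene interaction edge list
#'
#' Pre-exported undirected interaction evidence linking each query gene to
#' its known suppressors, plus decoy edges, standing in for a database
#' export.
#'
#' @return data.frame `gene_a`, `gene_b`, `evidence`.
#' @export
default_edges <- function() {
  data.frame(
    gene_a = c("SEC17", "SEC17", "SEC17", "TAO3", "TAO3", "TAO3",
                "GLN1", "GLN1", "SEC18", "CWP2"),
    gene_b = c("SEC18", "SCT1", "SEC22", "SIM1", "SSD1", "CWP2",
                "LUG1", "PMR1", "SEC22", "SSD1"),
    evidence = c("physical", "genetic", "genetic", "genetic", "genetic",
                  "genetic", "genetic", "genetic", "physical", "genetic"),
    stringsAsFactors = FALSE)
}
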