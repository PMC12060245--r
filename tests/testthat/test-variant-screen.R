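# The filter chain: VCF dialect handling, the three filters and their
# boundaries, chain algebra, and full-cohort recovery of planted truth.

make_records <- function(pos, qual, strain = "s1", chrom = "chrI",
                         ref = "A", alt = "T") {
  data.frame(strain = strain, chrom = chrom, pos = pos, ref = ref, alt = alt,
              qual = qual, qual_missing = is.na(qual), stringsAsFactors = FALSE)
}

write_test_vcf <- function(lines, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), path)
  path
}

test_that("read_vcf splits multiallelics and flags missing QUAL", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(character(0), p)
  expect_equal(nrow(read_vcf(p)), 0L)

  write_test_vcf("chrI\t100\t.\tA\tT\t250\tPASS\t.", p)
  v <- read_vcf(p, strain = "x")
  expect_equal(v$pos, 100L)
  expect_equal(v$ref, "A"); expect_equal(v$alt, "T")
  expect_equal(v$qual, 250)
  expect_false(v$qual_missing)

  write_test_vcf(c("chrI\t100\t.\tA\tT,G\t250\tPASS\t.",
                   "chrII\t7\t.\tC\tG\t.\tPASS\t."), p)
  v <- read_vcf(p)
  expect_equal(nrow(v), 3L)                      # multiallelic split
  expect_equal(v$alt[v$pos == 100], c("T", "G"))
  expect_true(v$qual_missing[v$pos == 7])        # QUAL '.' flagged
})

test_that("quality filter removes strictly below the Phred threshold", {
  r <- make_records(pos = 1:4, qual = c(199.9, 200, 500, NA))
  out <- filter_quality(r, filter_config(min_quality = 200))
  expect_equal(out$kept$pos, c(2L, 3L))          # 199.9 removed, 200 kept
  expect_equal(out$n_quality_missing, 1L)
  empty <- filter_quality(r[0, ], filter_config())
  expect_equal(nrow(empty$kept), 0L)
})

test_that("parental subtraction removes by identity, not quality or strain", {
  sup <- make_records(pos = c(10L, 20L), qual = c(300, 300))
  par <- list(p1 = make_records(pos = 10L, qual = 50, strain = "p1"))
  out <- subtract_parental(sup, par)
  expect_equal(out$kept$pos, 20L)
  expect_equal(out$removed$pos, 10L)
  # suppressor set equal to parent set -> empty result
  out2 <- subtract_parental(sup, list(p1 = transform(sup, strain = "p1")))
  expect_equal(nrow(out2$kept), 0L)
  # empty parental list warns and passes through
  expect_warning(out3 <- subtract_parental(sup, list()), "pass-through")
  expect_equal(out3$kept, sup)
})

test_that("matched-parent scope consults only the strain's own parent", {
  sup <- rbind(make_records(10L, 300, strain = "s1"),
               make_records(10L, 300, strain = "s2"))
  pars <- list(pA = make_records(10L, 300, strain = "pA"),
               pB = make_records(99L, 300, strain = "pB"))
  cfg <- filter_config(parental_scope = "matched_parent")
  out <- subtract_parental(sup, pars, cfg,
                           matched_parent = c(s1 = "pA", s2 = "pB"))
  expect_equal(out$kept$strain, "s2")   # s1's variant is in its parent pA
  expect_equal(out$removed$strain, "s1")
})

test_that("recurrence filter removes identities in more than 3 strains", {
  shared4 <- do.call(rbind, lapply(paste0("s", 1:4), function(s)
    make_records(50L, 300, strain = s)))
  shared3 <- do.call(rbind, lapply(paste0("s", 1:3), function(s)
    make_records(60L, 300, strain = s, alt = "G")))
  private <- make_records(70L, 300, strain = "s1", alt = "C")
  all <- rbind(shared4, shared3, private)
  out <- filter_recurrent(all, filter_config(max_recurrence = 3L))
  expect_false(any(out$kept$pos == 50L))         # 4 strains: removed everywhere
  expect_equal(sum(out$kept$pos == 60L), 3L)     # exactly 3 strains: kept
  expect_equal(sum(out$kept$pos == 70L), 1L)
  # single-strain cohort: untouched
  single <- filter_recurrent(private, filter_config())
  expect_equal(single$kept, private)
})

test_that("filter chain is idempotent and conserves records", {
  set.seed(31)
  recs <- make_records(pos = sample.int(1e5, 60), qual = runif(60, 0, 600),
                        strain = sample(paste0("s", 1:6), 60, replace = TRUE))
  cfg <- filter_config()
  par <- list(p = make_records(pos = recs$pos[1:10], qual = 300, strain = "p"))
  q1 <- filter_quality(recs, cfg)
  expect_equal(nrow(q1$kept) + nrow(q1$removed), nrow(recs))
  p1 <- subtract_parental(q1$kept, par, cfg)
  expect_equal(nrow(p1$kept) + nrow(p1$removed), nrow(q1$kept))
  r1 <- filter_recurrent(p1$kept, cfg)
  expect_equal(nrow(r1$kept) + nrow(r1$removed), nrow(p1$kept))
  # idempotence: a second pass removes nothing
  q2 <- filter_quality(r1$kept, cfg)
  p2 <- subtract_parental(q2$kept, par, cfg)
  r2 <- filter_recurrent(p2$kept, cfg)
  expect_identical(r2$kept, r1$kept)
  # quality and parental subtraction commute
  alt_order <- filter_quality(subtract_parental(recs, par, cfg)$kept, cfg)$kept
  expect_identical(sort(supscan:::variant_id(alt_order)),
                   sort(supscan:::variant_id(p1$kept)))
})

test_that("run_screen recovers exactly the planted suppressor events", {
  co <- cached_cohort()
  res <- cached_pipeline()
  truth <- co$truth$snvs
  got <- res$screen$survivors
  truth_key <- paste(truth$strain, truth$chrom, truth$pos, truth$ref, truth$alt)
  got_key <- paste(got$strain, got$chrom, got$pos, got$ref, got$alt)
  expect_setequal(got_key, truth_key)            # precision = recall = 1
  # surviving consequence categories equal the planted categories
  m <- match(got_key, truth_key)
  expect_equal(got$category, truth$category[m])
  # cohort category totals mirror the planted 5 intergenic /
  # 8 stop-or-frameshift / 10 missense structure
  tab <- table(got$category)
  expect_equal(unname(tab["intergenic"]), 5L)
  expect_equal(unname(tab["nonsense"] + tab["frameshift"]), 8L)
  expect_equal(unname(tab["missense"]), 10L)
  # ledger conserves counts through the chain
  led <- res$screen$ledger
  expect_equal(led$n_in[led$stage == "input"] -
                 sum(led$n_removed), nrow(got))
})

test_that("a cohort whose every variant is parental screens to empty", {
  g <- toy_genome(seed = 8)
  par <- data.frame(strain = "p", chrom = "tA", pos = c(5L, 9L),
                     ref = c("A", "C"), alt = c("T", "G"),
                     qual = c(400, 400), qual_missing = FALSE)
  sup <- transform(par, strain = "s1")
  res <- run_screen(list(s1 = sup), list(p = par))
  expect_equal(nrow(res$survivors), 0L)
})
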