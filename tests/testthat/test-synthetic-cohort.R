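# The synthetic-cohort generator: divergence model, depth model, colony
# model, emission determinism and round-trippability.

test_that("natural-isolate divergence follows its binomial expectation", {
  g <- default_genome(scale = 0.1)
  ref <- synth_reference(g, seed = 2)
  expect_equal(nrow(generate_natural_isolate(
    g, ref, strain_profile("zero", 0), seed = 1)), 0L)

  total <- sum(g$chromosomes$length)
  rate <- 0.0040
  v <- generate_natural_isolate(g, ref, strain_profile("L-1374", rate), seed = 3)
  sd_bin <- sqrt(total * rate * (1 - rate))
  expect_lt(abs(nrow(v) - total * rate), 3 * sd_bin)
  # measured divergence = count / genome length recovers the profile rate
  expect_equal(nrow(v) / total, rate, tolerance = 3 * sd_bin / (rate * total))
  expect_true(all(v$ref != v$alt))
  expect_true(all(v$qual >= 200))
  # deterministic under the seed
  v2 <- generate_natural_isolate(g, ref, strain_profile("L-1374", rate), seed = 3)
  expect_identical(v, v2)
  expect_error(strain_profile("x", 0.2), "out of range")
})

test_that("depth model puts a planted disomy at twice the genome median", {
  g <- default_genome(scale = 0.1)
  spec <- depth_track_spec(window_size = 3000L)
  aneu <- data.frame(strain = "s", chrom = "chrII", start = 0,
                      end = g$chromosomes$length[2], copy_number = 2L,
                      kind = "full")
  w <- supscan:::simulate_depth_track(g, spec, aneu, base_ploidy = 1L, seed = 5)
  med <- median(w$mean_depth[w$chrom != "chrII"])
  expect_equal(mean(w$mean_depth[w$chrom == "chrII"]) / med, 2, tolerance = 0.1)
  # declared-noisy chromosomes get visibly higher relative spread
  spread <- tapply(w$mean_depth[w$copy_number_truth == 1],
                   w$chrom[w$copy_number_truth == 1],
                   function(x) sd(x) / mean(x))
  expect_gt(mean(spread[c("chrI", "chrIII", "chrVI")], na.rm = TRUE),
            mean(spread[setdiff(names(spread), c("chrI", "chrIII", "chrVI", "chrII"))],
                 na.rm = TRUE))
})

test_that("colony sizes recover their planted effects", {
  eff <- data.frame(background = "b", genotype = c("control", "null", "sup"),
                     temperature_C = 36, plasmid = "none",
                     effect = c(1, 1, 2), control_mean = 1000)
  colonies <- simulate_colony_sizes(eff, n_colonies = 400L, sdlog = 0.1,
                                    seed = 8)
  m <- tapply(colonies$colony_size, colonies$genotype, mean)
  expect_equal(unname(m["null"] / m["control"]), 1, tolerance = 0.03)
  expect_equal(unname(m["sup"] / m["control"]), 2, tolerance = 0.06)
  expect_error(simulate_colony_sizes(transform(eff, effect = -1)), "> 0")
})

test_that("cohort emission is byte-identical under a fixed seed", {
  g <- default_genome(scale = 0.02)
  spec <- depth_track_spec(window_size = 600L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  emit_cohort(d1, genome = g, seed = 99, depth_spec = spec, n_colonies = 10L,
              n_noise = 5L, use_backcross_blocks = FALSE)
  emit_cohort(d2, genome = g, seed = 99, depth_spec = spec, n_colonies = 10L,
              n_noise = 5L, use_backcross_blocks = FALSE)
  h1 <- dir_md5(d1); h2 <- dir_md5(d2)
  expect_identical(names(h1), names(h2))
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the content
  d3 <- file.path(tempdir(), "det3")
  unlink(d3, recursive = TRUE)
  emit_cohort(d3, genome = g, seed = 100, depth_spec = spec, n_colonies = 10L,
              n_noise = 5L, use_backcross_blocks = FALSE)
  expect_false(identical(unname(dir_md5(d3)), unname(h1)))
})

test_that("emitted files round-trip through the pipeline readers", {
  co <- cached_cohort()
  # VCF: a parent set re-read equals what was planted for it
  v <- read_vcf(co$vcfs[[co$parents[1]]])
  expect_gt(nrow(v), 0L)
  expect_true(all(c("strain", "chrom", "pos", "ref", "alt", "qual") %in% names(v)))
  # depth: windows tile chromosomes without gaps
  w <- read_depth_track(co$depth[[1]])
  by_chr <- split(w, w$chrom)
  for (b in by_chr) expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  # ploidy, colonies, counts parse and carry the consumed columns
  pl <- read_ploidy(co$ploidy)
  expect_setequal(pl$strain, read_tsv_manifest(co$manifest)$strain)
  counts <- read_counts(co$counts)
  expect_true(all(counts$raw_count >= 0))
  # truth JSON records the seed and every planted event class
  truth <- jsonlite::read_json(co$truth_json, simplifyVector = TRUE)
  expect_equal(truth$seed, 42)
  expect_equal(nrow(truth$snvs), 23L)
  expect_equal(sort(unique(truth$strains$class)),
               sort(c("euploid_snp", "aneuploid_only", "snp_and_aneuploid",
                      "unexplained")))
})

test_that("planted cohort carries the three contaminating call classes", {
  co <- cached_cohort()
  manifest <- read_tsv_manifest(co$manifest)
  s1 <- manifest$strain[1]
  sup <- read_vcf(co$vcfs[[s1]], strain = s1)
  par <- read_vcf(co$vcfs[[manifest$parent[1]]])
  vid <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  # (i) parental-background variants shared with the matched parent
  expect_gt(length(intersect(vid(sup), vid(par))), 0L)
  # (ii) low-quality noise strictly below the Phred 200 boundary
  expect_gt(sum(sup$qual < 200), 0L)
  # (iii) >=1 artifact present in more than 3 suppressor strains
  truth <- co$truth
  strain_ids <- lapply(manifest$strain, function(s) {
    vid(read_vcf(co$vcfs[[s]], strain = s))
  })
  counts <- vapply(truth$artifact_ids, function(id) {
    sum(vapply(strain_ids, function(ids) id %in% ids, logical(1)))
  }, numeric(1))
  expect_true(any(counts > 3))
})
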