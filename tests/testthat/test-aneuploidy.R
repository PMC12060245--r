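# Depth normalization, ploidy correction, segmentation and aneuploidy
# calling, including recovery of planted events on seeded strains.

flat_windows <- function(chroms = c(cA = 20L, cB = 12L), depth = 100,
                         window = 1000L) {
  do.call(rbind, lapply(names(chroms), function(ch) {
    n <- chroms[[ch]]
    data.frame(chrom = ch, start = (0:(n - 1)) * window,
                end = (1:n) * window, mean_depth = depth)
  }))
}

test_that("relative depth normalizes to the genome median and is scale-free", {
  w <- flat_windows()
  out <- normalize_depth(w)
  expect_true(all(out$relative_depth == 1))
  # a duplicated minority chromosome sits at ~2
  w2 <- w; w2$mean_depth[w2$chrom == "cB"] <- 200
  out2 <- normalize_depth(w2)
  expect_true(all(out2$relative_depth[out2$chrom == "cB"] == 2))
  # scaling every depth leaves relative depth unchanged
  w3 <- w2; w3$mean_depth <- w3$mean_depth * 17
  expect_equal(normalize_depth(w3)$relative_depth, out2$relative_depth)
  expect_error(normalize_depth(transform(w, mean_depth = 0)), "median")
})

test_that("ploidy correction turns relative depth into copy estimates", {
  w <- normalize_depth(flat_windows())
  w$relative_depth <- 2
  expect_equal(unique(ploidy_correct(w, 1.0)$copy_estimate), 2)
  w$relative_depth <- 1.5
  expect_equal(unique(ploidy_correct(w, 2.0)$copy_estimate), 3)
  # a euploid diploid chromosome sits at copy 2 (twice a haploid's 1)
  w$relative_depth <- 1
  expect_equal(unique(ploidy_correct(w, 1.96)$copy_estimate), 2)
  expect_error(ploidy_correct(w, 1.4), "fractional")
  expect_error(ploidy_correct(w, 0.2), "rounds below 1|fractional")
})

test_that("segmentation finds runs and absorbs sub-minimum noise", {
  w <- normalize_depth(flat_windows(c(cA = 20L)))
  w <- ploidy_correct(w, 1.0)
  seg <- segment_copy_number(w)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$copy_number, 1L)
  # right half duplicated: two segments with breakpoint at the truth
  w2 <- w; w2$copy_estimate[11:20] <- 2
  seg2 <- segment_copy_number(w2)
  expect_equal(seg2$copy_number, c(1L, 2L))
  expect_equal(seg2$end[1], w$end[10])
  # one isolated 2x window inside a CN=1 run is absorbed
  w3 <- w; w3$copy_estimate[7] <- 2
  seg3 <- segment_copy_number(w3)
  expect_equal(nrow(seg3), 1L)
  expect_equal(seg3$copy_number, 1L)
  # segments tile the chromosome
  expect_equal(sum(seg2$end - seg2$start), sum(w$end - w$start))
})

test_that("calls distinguish full from segmental and gain from loss", {
  seg <- data.frame(chrom = "cA", start = 0, end = 600000, copy_number = 2L,
                     relative_depth = 2, n_windows = 20L)
  call <- call_aneuploidies(seg, base_ploidy = 1L, strain = "s")
  expect_equal(call$kind, "full")
  expect_equal(call$direction, "gain")
  expect_equal(call$copy_number, 2L)
  # terminal 300-kb region on a 1-Mb chromosome is segmental
  seg2 <- data.frame(chrom = "cA", start = c(0, 7e5), end = c(7e5, 1e6),
                      copy_number = c(1L, 2L), relative_depth = c(1, 2),
                      n_windows = c(23L, 10L))
  call2 <- call_aneuploidies(seg2, base_ploidy = 1L)
  expect_equal(call2$kind, "segmental")
  expect_equal(call2$extent_fraction, 0.3)
  # losses
  seg3 <- transform(seg, copy_number = 1L)
  call3 <- call_aneuploidies(seg3, base_ploidy = 2L)
  expect_equal(call3$direction, "loss")
  # euploid genome: empty call set
  expect_equal(nrow(call_aneuploidies(seg3, base_ploidy = 1L)), 0L)
})

test_that("noise flagging reports over-dispersed chromosomes", {
  set.seed(44)
  w <- flat_windows(c(cA = 60L, cB = 60L, cC = 60L))
  w$mean_depth <- rnorm(nrow(w), 100, 3)
  w$mean_depth[w$chrom == "cC"] <- rnorm(60, 100, 18)
  out <- flag_noisy(normalize_depth(w))
  expect_false(any(out$flagged[out$chrom %in% c("cA", "cB")]))
  expect_true(out$flagged[out$chrom == "cC"])
  # homogeneous noise: nothing flagged
  w$mean_depth <- rnorm(nrow(w), 100, 5)
  expect_false(any(flag_noisy(normalize_depth(w))$flagged))
})

test_that("planted events are recovered with correct labels across ploidies", {
  # 20 seeded strains on a 4-chromosome frame at 100x / 30-kb windows;
  # planted full and segmental CN+/-1 events all span >= 120 kb
  chroms <- data.frame(name = c("w1", "w2", "w3", "w4"),
                        length = c(900000L, 600000L, 450000L, 300000L))
  genome <- genome_model(chroms, map_cM = 1000)
  spec <- depth_track_spec(window_size = 30000L,
                            noisy_chromosomes = character(0))
  for (i in 1:20) {
    base_ploidy <- if (i %% 2 == 0) 2L else 1L
    kind <- c("none", "full_gain", "seg_gain", "seg_loss", "full_gain")[(i %% 5) + 1]
    aneu <- switch(kind,
      none = NULL,
      full_gain = data.frame(strain = "s", chrom = "w2", start = 0,
                              end = 600000, copy_number = base_ploidy + 1L),
      seg_gain = data.frame(strain = "s", chrom = "w1", start = 600000,
                             end = 900000, copy_number = base_ploidy + 1L),
      seg_loss = data.frame(strain = "s", chrom = "w1", start = 0,
                             end = 150000, copy_number = base_ploidy - 1L))
    if (!is.null(aneu) && any(aneu$copy_number < 0)) aneu <- NULL
    w <- supscan:::simulate_depth_track(genome, spec, aneu, base_ploidy,
                                        seed = 500 + i)
    w <- ploidy_correct(normalize_depth(w), base_ploidy)
    seg <- segment_copy_number(w)
    calls <- call_aneuploidies(seg, base_ploidy, strain = paste0("s", i))
    if (is.null(aneu)) {
      expect_equal(nrow(calls), 0L)
    } else {
      expect_equal(nrow(calls), 1L)              # precision & recall = 1
      expect_equal(calls$chrom, aneu$chrom)
      expect_equal(calls$copy_number, aneu$copy_number)
      expect_equal(calls$kind,
                   if (startsWith(kind, "full")) "full" else "segmental")
      expect_equal(calls$direction,
                   if (aneu$copy_number > base_ploidy) "gain" else "loss")
      if (calls$kind == "segmental") {
        # breakpoints land within two windows of the truth
        expect_lte(abs(calls$start - aneu$start), 2 * 30000)
        expect_lte(abs(calls$end - aneu$end), 2 * 30000)
      }
    }
  }
})

test_that("one extra copy reads as CN 2 in a haploid and CN 3 in a diploid", {
  chroms <- data.frame(name = c("w1", "w2"), length = c(900000L, 300000L))
  genome <- genome_model(chroms, map_cM = 500)
  spec <- depth_track_spec(window_size = 30000L,
                            noisy_chromosomes = character(0))
  for (bp in c(1L, 2L)) {
    aneu <- data.frame(strain = "s", chrom = "w2", start = 0, end = 300000,
                        copy_number = bp + 1L)
    w <- supscan:::simulate_depth_track(genome, spec, aneu, bp, seed = 77)
    w <- ploidy_correct(normalize_depth(w), bp)
    calls <- call_aneuploidies(segment_copy_number(w), bp, strain = "s")
    expect_equal(calls$copy_number, bp + 1L)
  }
})

test_that("raw-depth scaling changes no call", {
  co <- cached_cohort()
  w <- read_depth_track(co$depth[[1]])
  calls1 <- call_aneuploidies(
    segment_copy_number(ploidy_correct(normalize_depth(w), 1.0)), 1L)
  w$mean_depth <- w$mean_depth * 3.7
  calls2 <- call_aneuploidies(
    segment_copy_number(ploidy_correct(normalize_depth(w), 1.0)), 1L)
  expect_equal(calls1, calls2)
})

test_that("calls on flagged chromosomes carry a low-confidence annotation", {
  seg <- data.frame(chrom = "chrI", start = 0, end = 200000,
                     copy_number = 2L, relative_depth = 2, n_windows = 7L)
  call <- call_aneuploidies(seg, 1L, strain = "s",
                            noisy_chromosomes = "chrI")
  expect_equal(call$confidence, "low")
  call2 <- call_aneuploidies(seg, 1L, strain = "s")
  expect_equal(call2$confidence, "high")
})
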