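# Colony-size statistics: fold changes, Welch tests vs the textbook
# oracle, Bonferroni, wild-type normalization, Tukey HSD behaviour and the
# conservation matrix.

test_that("fold change is the ratio of sample means", {
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fold_change(c(2, 4), c(1, 2)), 2)
  expect_equal(fold_change(c(30, 50, 70), c(10, 20, 30)), 2.5)
  expect_error(fold_change(numeric(0), 1), "empty")
  expect_error(fold_change(c(-1, 2), c(1, 2)), "positive")
  # invariant under a common positive rescaling
  expect_equal(fold_change(7 * c(30, 50, 70), 7 * c(10, 20, 30)), 2.5)
})

test_that("welch_one_sided matches the textbook formula oracle", {
  # identical samples (up to jitter-free symmetry): t = 0, p = 0.5
  x <- c(1, 2, 3, 4)
  w0 <- welch_one_sided(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 0.5)
  # 1000 random draws with varying n and variance ratios, equality to 1e-8
  set.seed(71)
  for (i in 1:1000) {
    nx <- sample(3:40, 1); ny <- sample(3:40, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3))
    y <- rnorm(ny, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welch_one_sided(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-8)
    expect_equal(got$df, want$df, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
  # a strong true effect at n = 100 is overwhelming
  set.seed(72)
  big <- welch_one_sided(rnorm(100, 10), rnorm(100, 0))
  expect_lt(big$p, 1e-10)
  # scale invariance of t and p
  set.seed(73)
  a <- rlnorm(20); b <- rlnorm(20)
  expect_equal(welch_one_sided(5 * a, 5 * b)$p, welch_one_sided(a, b)$p)
  expect_error(welch_one_sided(1, c(1, 2)), "n >= 2")
})

test_that("bonferroni caps at one and preserves order", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.3, 1), 0.3)
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroni(p, 8)
  expect_true(all(diff(adj) >= 0))               # monotone
  expect_true(all(adj >= p))
  expect_error(bonferroni(c(0.1, 0.2), 1), "family_size")
})

test_that("wild-type normalization divides by the background median", {
  colonies <- data.frame(
    background = rep(c("b1", "b2"), each = 4),
    genotype = rep(c("wild-type", "wild-type", "mut", "mut"), 2),
    colony_size = c(10, 20, 7.5, 15, 100, 200, 30, 60))
  out <- normalize_to_wildtype(colonies)
  expect_equal(median(out$normalized_size[out$genotype == "wild-type" &
                                            out$background == "b1"]), 1)
  expect_equal(out$normalized_size[out$genotype == "mut" & out$background == "b1"],
               c(0.5, 1.0))
  # invariant to rescaling a whole background's plate
  colonies2 <- colonies
  sel <- colonies2$background == "b2"
  colonies2$colony_size[sel] <- colonies2$colony_size[sel] * 3
  out2 <- normalize_to_wildtype(colonies2)
  expect_equal(out2$normalized_size, out$normalized_size)
  expect_error(normalize_to_wildtype(transform(colonies, genotype = "mut")),
               "wild-type")
})

test_that("tukey_combinations controls the null and finds shifted groups", {
  # under one shared distribution, some replicate shows any significant
  # pair at about the family-wise alpha
  set.seed(81)
  any_sig <- vapply(1:200, function(r) {
    sizes <- rnorm(60, 1, 0.2)
    groups <- rep(c("A", "B", "A+B", "A+C"), each = 15)
    tk <- tukey_combinations(sizes, groups)
    any(tk$pairs$p_adj < 0.05)
  }, logical(1))
  expect_lt(mean(any_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  # a +5 SD group beats every other group
  set.seed(82)
  sizes <- c(rnorm(15, 1, 0.2), rnorm(15, 1, 0.2), rnorm(15, 2, 0.2))
  groups <- rep(c("A", "B", "A+B"), each = 15)
  tk <- tukey_combinations(sizes, groups)
  shifted <- tk$pairs[grepl("A\\+B", tk$pairs$group_a) |
                        grepl("A\\+B", tk$pairs$group_b), ]
  expect_true(all(shifted$p_adj < 0.05))
  # the multi-vs-single report contains both single-gene comparisons
  expect_setequal(tk$multi_exceeds_single$single_group, c("A", "B"))
  # two identical groups: adjusted p near 1
  sizes2 <- c(rnorm(15, 1, 0.2), rnorm(15, 1, 0.2) )
  set.seed(83)
  sizes2 <- rep(rnorm(15, 1, 0.2), 2)
  tk2 <- tukey_combinations(sizes2, rep(c("A", "B"), each = 15))
  expect_gt(tk2$pairs$p_adj, 0.99)
})

test_that("best_condition maximizes fold change with the stated tie-breaks", {
  res <- data.frame(suppressor = "S", background = "b",
                     temperature_C = c(34, 36, 38), plasmid = "CEN",
                     fold_change = c(1.2, 3.0, 2.1), t = 1, df = 10,
                     p_value = c(0.2, 0.001, 0.01),
                     p_adjusted = c(0.6, 0.003, 0.03),
                     suppressed = c(FALSE, TRUE, TRUE))
  expect_equal(best_condition(res)$temperature_C, 36)
  # exact fold tie: the lower adjusted p wins
  res$fold_change <- c(3.0, 3.0, 2.1)
  res$p_adjusted <- c(0.5, 0.003, 0.03)
  expect_equal(best_condition(res)$temperature_C, 36)
  # single condition returns itself
  expect_equal(best_condition(res[1, ])$temperature_C, 34)
})

test_that("null colony data stays under the alpha false-call budget", {
  # effect = 1 everywhere; Bonferroni across the 4-test family; the
  # family-wise false "suppressed" rate must stay at or below alpha
  eff <- expand.grid(background = paste0("b", 1:4),
                      genotype = c("control", "S"),
                      stringsAsFactors = FALSE)
  eff$temperature_C <- 36; eff$plasmid <- "none"
  eff$effect <- 1; eff$control_mean <- 1000
  false_call <- vapply(1:500, function(r) {
    colonies <- simulate_colony_sizes(eff, n_colonies = 20L, sdlog = 0.25,
                                      seed = 9000 + r)
    any(suppression_tests(colonies)$suppressed)
  }, logical(1))
  expect_lte(mean(false_call), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("planted fold effects are recovered within 10% at n = 100", {
  eff <- data.frame(background = "b",
                     genotype = c("control", "s1", "s2", "s3"),
                     temperature_C = 36, plasmid = "none",
                     effect = c(1, 1.5, 2, 3), control_mean = 1000)
  colonies <- simulate_colony_sizes(eff, n_colonies = 100L, sdlog = 0.1,
                                    seed = 91)
  res <- suppression_tests(colonies)
  got <- setNames(res$fold_change, res$suppressor)
  expect_equal(unname(got[c("s1", "s2", "s3")]), c(1.5, 2, 3),
               tolerance = 0.1)
})

test_that("the planted conservation structure reads out as 10 of 11", {
  res <- cached_pipeline()
  cons <- res$conservation
  expect_equal(cons$n_tested, 11L)
  expect_equal(cons$n_conserved, 10L)
  # the one non-conserved interaction fails in exactly one background
  not_cons <- names(cons$conserved)[!cons$conserved]
  expect_equal(length(not_cons), 1L)
  row <- cons$matrix[not_cons, ]
  expect_equal(sum(!row), 1L)
  # all-null effects give zero conserved
  eff <- expand.grid(background = c("b1", "b2"),
                      genotype = c("control", "S"), stringsAsFactors = FALSE)
  eff$temperature_C <- 36; eff$plasmid <- "none"
  eff$effect <- 1; eff$control_mean <- 1000
  colonies <- simulate_colony_sizes(eff, n_colonies = 50L, seed = 17)
  cons0 <- conservation_matrix(suppression_tests(colonies))
  expect_equal(cons0$n_conserved, 0L)
})
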