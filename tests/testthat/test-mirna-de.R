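# Two-channel normalization and time-course differential expression.

test_that("lowess normalization removes dye bias and is stable", {
  # equal channels: M is identically zero before and after
  set.seed(1)
  hy <- matrix(2^rnorm(300, 8), 50)
  arr <- two_channel_array(hy, hy, rep(c("D0", "D7", "D13"), each = 2))
  expect_lt(max(abs(lowess_normalize(arr))), 1e-12)

  # planted cubic bias, no DE: per-decile |mean M| < 0.05 after normalization
  cfg <- small_cfg(n_mirnas = 500L, n_de_mirnas = 0L,
                   dye_bias_amplitude = 0.3, rng_seed = 4L)
  sim <- gen_mirna_arrays(cfg)
  m <- lowess_normalize(sim$array)
  a <- (log2(sim$array$hy3) + log2(sim$array$hy5)) / 2
  dec <- cut(as.vector(a), quantile(a, 0:10 / 10), include.lowest = TRUE)
  expect_lt(max(abs(tapply(as.vector(m), dec, mean))), 0.05)
  # and the bias was really there beforehand
  m_raw <- log2(sim$array$hy3) - log2(sim$array$hy5)
  expect_gt(max(abs(tapply(as.vector(m_raw), dec, mean))), 0.02)

  # exact idempotence when M is constant; bounded second-pass change with noise
  cfg0 <- small_cfg(n_mirnas = 200L, n_de_mirnas = 0L,
                    dye_bias_amplitude = 0, rng_seed = 3L)
  sim0 <- gen_mirna_arrays(cfg0)
  m1 <- lowess_normalize(sim0$array)
  arr2 <- two_channel_array(sim0$array$hy5 * 2^m1, sim0$array$hy5,
                            sim0$array$timepoint)
  m2 <- lowess_normalize(arr2)
  expect_lt(sqrt(mean((m2 - m1)^2)), 0.1 * sqrt(mean(m1^2)))

  expect_error(lowess_normalize(sim0$array, span = 0), "span")
  expect_error(lowess_normalize(sim0$array, span = 1.5), "span")
  expect_error(two_channel_array(matrix(c(1, -1, 2, 3), 2), matrix(1, 2, 2),
                                 c("D0", "D0")), "non-positive")
})

test_that("per-probe one-way ANOVA matches its classical definitions", {
  set.seed(1)
  # two groups: F = t^2, P-values agree with the pooled t-test
  m <- matrix(rnorm(50 * 8), 50)
  g <- rep(c("a", "b"), each = 4)
  p_anova <- anova_per_probe(m, g)
  p_t <- apply(m, 1, function(x) {
    t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)$p.value
  })
  expect_equal(unname(p_anova), p_t, tolerance = 1e-10)

  # three groups: agrees with anova(lm()) probe by probe
  m3 <- matrix(rnorm(10 * 9), 10)
  g3 <- rep(c("D0", "D7", "D13"), each = 3)
  p3 <- anova_per_probe(m3, g3)
  p_lm <- apply(m3, 1, function(x) {
    anova(lm(x ~ factor(g3)))[["Pr(>F)"]][1]
  })
  expect_equal(unname(p3), p_lm, tolerance = 1e-12)

  # all observations identical: P = 1 by convention
  expect_equal(unname(anova_per_probe(matrix(5, 1, 6),
                                      rep(c("a", "b", "c"), each = 2))), 1)
  # zero within-group variance with a real difference: P = 0
  expect_equal(unname(anova_per_probe(matrix(c(1, 1, 2, 2), 1),
                                      c("a", "a", "b", "b"))), 0)

  # null P-values are uniform (Kolmogorov-Smirnov at alpha = 0.01)
  set.seed(2)
  mn <- matrix(rnorm(1000 * 9), 1000)
  pn <- anova_per_probe(mn, rep(c("D0", "D7", "D13"), each = 3))
  expect_gt(ks.test(pn, "punif")$p.value, 0.01)

  expect_error(anova_per_probe(m, rep("a", 8)), "2 groups")
  expect_error(anova_per_probe(m, c(rep("a", 7), "b")), "per group")
})

test_that("Bonferroni adjustment follows the capped definition", {
  expect_equal(bonferroni_adjust(c(0.01, 0.5, 0.2)),
               c(0.03, 1, 0.6))
  expect_equal(bonferroni_adjust(rep(0.9, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bonferroni_adjust(p), bf_bonferroni(p))
    expect_true(all(bonferroni_adjust(p) >= p))
  }
  expect_error(bonferroni_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Tukey HSD behaves like the studentized-range procedure", {
  # identical group data: all pairwise differences zero, adjusted P ~ 1
  vals <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  tk <- tukey_hsd(vals, g)
  expect_equal(nrow(tk), 3L)
  expect_equal(tk$mean_diff, rep(0, 3))
  expect_true(all(tk$adjusted_p > 0.999))

  # two balanced groups: Tukey reduces to the unadjusted t-test
  set.seed(4)
  x <- rnorm(12)
  g2 <- rep(c("a", "b"), each = 6)
  tk2 <- tukey_hsd(x, g2)
  pt2 <- t.test(x[g2 == "b"], x[g2 == "a"], var.equal = TRUE)$p.value
  expect_equal(tk2$adjusted_p, pt2, tolerance = 1e-8)

  # a single shifted group dominates the smallest adjusted P-values
  set.seed(5)
  hits <- replicate(40, {
    y <- c(rnorm(4), rnorm(4), rnorm(4, mean = 3))
    gg <- rep(c("D0", "D7", "D13"), each = 4)
    tk3 <- tukey_hsd(y, gg)
    top2 <- tk3$pair[order(tk3$adjusted_p)][1:2]
    all(grepl("D13", top2))
  })
  expect_gte(mean(hits), 0.95)

  expect_error(tukey_hsd(c(1, 2, 3), c("a", "b", "b")), "2 observations")
})

test_that("the day-13 table filter reproduces the published 38-miRNA set", {
  fx <- load_fixtures()
  hits <- call_de_mirnas(fx$table1, alpha = 0.05)
  expect_equal(nrow(hits), 38L)
  expect_equal(max(hits$adj_p_value), 0.043)
  expect_equal(hits$annotation[which.max(hits$adj_p_value)], "hsa-miR-30d")
  # ordering by ascending raw P is preserved
  expect_identical(hits$annotation, fx$table1$annotation)
  expect_false(is.unsorted(hits$p_value))
  # filter and adjustment are equivariant under row permutation
  set.seed(6)
  shuf <- fx$table1[sample(nrow(fx$table1)), ]
  expect_identical(call_de_mirnas(shuf), hits)
  # empty input stays empty
  expect_equal(nrow(call_de_mirnas(fx$table1[0, ])), 0L)
})

test_that("linear fold changes match the published miR-320 range", {
  expect_equal(fold_change_linear(0), 1)
  expect_equal(fold_change_linear(1.200823), 2.298, tolerance = 1e-3)
  fx <- load_fixtures()
  m320 <- fx$table1[fx$table1$annotation %in%
                      paste0("hsa-miR-320", c("a", "b", "c", "d", "e")), ]
  expect_equal(nrow(m320), 5L)
  folds <- fold_change_linear(m320$logFC)
  expect_gte(min(folds), 2.2)
  expect_lte(max(folds), 3.0)
})

test_that("the DE table round-trips through its TSV writer", {
  fx <- load_fixtures()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mirna_de_tsv(fx$table1, path)
  back <- read_mirna_de_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$table1))
})

test_that("the array stage recovers planted miRNAs with controlled error", {
  res <- vapply(1:3, function(s) {
    sim <- gen_mirna_arrays(sim_config(rng_seed = s))
    tab <- mirna_de_table(sim$array)
    hits <- call_de_mirnas(tab, alpha = 0.05)
    c(sens = mean(sim$truth$de_mirna_ids %in% hits$annotation),
      fp = sum(!hits$annotation %in% sim$truth$de_mirna_ids))
  }, numeric(2))
  expect_true(all(res["sens", ] >= 0.9))
  expect_lte(sum(res["fp", ] > 0), 1)
})
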