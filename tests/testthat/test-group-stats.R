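toy3 <- data.frame(
  g = rep(c("a", "b", "c"), each = 3),
  y = c(1, 2, 3, 11, 12, 13, 21, 22, 23)
)

test_that("Kruskal-Wallis H matches the hand rank computation", {
  # ranks 1..9, no ties: H = 12/(9*10) * 3 * ((2-5)^2 + (5-5)^2 + (8-5)^2)
  cmp <- kruskal_wallis(toy3, y, g)
  expect_equal(cmp$statistic, 7.2, tolerance = 1e-12)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  # identical groups: H = 0
  flat <- data.frame(g = rep(c("a", "b", "c"), each = 3), y = rep(1:3, 3))
  expect_equal(kruskal_wallis(flat, y, g)$statistic, 0, tolerance = 1e-12)
  # all values identical: p = 1 by convention, with a warning
  const <- data.frame(g = rep(c("a", "b", "c"), each = 3), y = rep(1, 9))
  expect_warning(cmp <- kruskal_wallis(const, y, g), "identical")
  expect_equal(cmp$p_value, 1)
  expect_equal(tidy(cmp)$p_value, 1)
})

test_that("Dunn post-hoc comparisons match the direct z formula", {
  ph <- dunn_posthoc(toy3, y, g)
  # independent computation: pooled ranks, no ties
  r <- rank(toy3$y)
  rm_ <- tapply(r, toy3$g, mean)
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  z_ab <- (rm_[["a"]] - rm_[["b"]]) / se
  expect_equal(ph$z[ph$group1 == "a" & ph$group2 == "b"], z_ab)
  # the extreme pair carries the smallest adjusted p
  expect_equal(which.min(ph$p_adjusted),
               which(ph$group1 == "a" & ph$group2 == "c"))
  # Bonferroni: adjusted >= raw, capped at 1
  expect_true(all(ph$p_adjusted >= ph$p_value))
  expect_true(all(ph$p_adjusted <= 1))
  # two identical groups inside a 3-group test: adjusted p = 1
  d <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                  y = c(1, 2, 3, 1, 2, 3, 50, 60, 70))
  ph <- dunn_posthoc(d, y, g)
  expect_equal(ph$p_adjusted[ph$group1 == "a" & ph$group2 == "b"], 1)
})

test_that("Mann-Whitney U has the exact small-sample distribution", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  cmp <- mann_whitney(d, y, g)
  expect_equal(cmp$statistic, 0)   # first group wins no pairs
  expect_equal(cmp$p_value, 0.1)   # 2/20 orderings as extreme
  # identical groups: p = 1
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(1:3, 2))
  expect_equal(mann_whitney(d, y, g)$p_value, 1)
  # U_A + U_B = n_A n_B on random instances
  set.seed(40)
  for (i in 1:10) {
    nA <- sample(3:12, 1); nB <- sample(3:12, 1)
    d <- data.frame(g = rep(c("a", "b"), c(nA, nB)),
                    y = rnorm(nA + nB))
    uA <- mann_whitney(d, y, g)$statistic
    d2 <- d; d2$g <- factor(d2$g, levels = c("b", "a"))
    uB <- mann_whitney(d2, y, g)$statistic
    expect_equal(uA + uB, nA * nB)
  }
})

test_that("two-group Kruskal-Wallis matches Mann-Whitney decisions", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:15, 2)
    d <- data.frame(g = rep(c("a", "b"), n),
                    y = c(rnorm(n[1]), rnorm(n[2], mean = runif(1, 0, 2))))
    kw <- kruskal_wallis(d, y, g)$p_value
    mw <- suppressWarnings(
      stats::wilcox.test(y ~ g, d, exact = FALSE, correct = FALSE))$p.value
    expect_equal(kw < 0.05, mw < 0.05)
  }
})

test_that("ROC analysis matches exhaustive pair counting and rank identity", {
  # perfectly separated scores
  d <- data.frame(s = c(1, 2, 3, 10, 11, 12),
                  y = rep(c("neg", "pos"), each = 3))
  r <- roc_youden(d, s, y, positive = "pos")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 10)

  # 3 concordant pairs of 4: AUC = 0.75
  d <- data.frame(s = c(1, 2, 3, 4), y = c(0, 1, 0, 1))
  expect_equal(roc_youden(d, s, y, positive = 1)$auc, 0.75)

  # AUC == U / (n1 n2), ties included, on random instances
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    s <- c(round(rnorm(n1, 1), 1), round(rnorm(n2), 1))  # rounding makes ties
    d <- data.frame(s = s, y = rep(c("pos", "neg"), c(n1, n2)))
    r <- roc_youden(d, s, y, positive = "pos")
    u <- sum(outer(s[1:n1], s[-(1:n1)], ">")) +
      0.5 * sum(outer(s[1:n1], s[-(1:n1)], "=="))
    expect_equal(r$auc, u / (n1 * n2), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    d2 <- d; d2$s <- exp(d$s)
    expect_equal(roc_youden(d2, s, y, positive = "pos")$auc, r$auc,
                 tolerance = 1e-12)
  }

  # labels independent of scores: AUC near 1/2
  set.seed(43)
  d <- data.frame(s = rnorm(2000), y = rep(c("pos", "neg"), 1000))
  expect_lt(abs(roc_youden(d, s, y, positive = "pos")$auc - 0.5), 0.05)

  # one class absent is a domain error
  d <- data.frame(s = 1:4, y = rep("pos", 4))
  expect_error(roc_youden(d, s, y, positive = "pos"), "both classes")
})

test_that("Youden ties break toward higher specificity", {
  # cutoffs below 2.5 and above in [2.5, 3.5) both give J = 0.5;
  # the higher cutoff has higher specificity and must win
  d <- data.frame(s = c(1, 3, 2, 4), y = c("neg", "neg", "pos", "pos"))
  r <- roc_youden(d, s, y, positive = "pos")
  expect_equal(r$specificity, 100)
  expect_gt(r$cutoff, 3)
})

test_that("voxelwise Pearson correlation respects the f band", {
  dims <- c(10, 10, 10)
  m <- roi_mask(array(TRUE, dims))
  set.seed(44)
  f_map <- array(runif(1000, 0, 0.5), dims)
  # self-correlation and anti-correlation
  expect_equal(voxelwise_pearson(f_map, f_map, m)$r, 1)
  expect_equal(voxelwise_pearson(f_map, -f_map + 1, m)$r, -1)
  # planted correlation 0.6 over 1e4 voxels
  dims2 <- c(22, 22, 22)
  n <- prod(dims2)
  m2 <- roi_mask(array(TRUE, dims2))
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  r <- voxelwise_pearson(array(x, dims2), array(y, dims2), m2)
  expect_lt(abs(r$r - 0.6), 0.03)
  # band restriction keeps only voxels with f in [25, 40] percent
  other <- array(rnorm(1000), dims)
  rb <- voxelwise_pearson(f_map, other, m, f_band = c(25, 40))
  expect_equal(rb$n_voxels, sum(f_map >= 0.25 & f_map <= 0.40))
  # too few voxels or zero variance: missing with a warning
  tiny <- roi_mask(array(c(TRUE, TRUE, rep(FALSE, 998)), dims))
  expect_warning(r <- voxelwise_pearson(f_map, other, tiny), "fewer than 3")
  expect_true(is.na(r$r))
  expect_warning(
    r <- voxelwise_pearson(array(0.3, dims), other, m), "zero variance")
  expect_true(is.na(r$r))
})

test_that("feature-table wrappers assemble per-cell results", {
  cohort <- generate_feature_cohort(c(HB = 4, NB = 11, W = 8),
                                    parameters = "f", seed = 45)
  out <- compare_feature_groups(cohort)
  expect_equal(nrow(out$omnibus), 9)
  expect_true(all(out$omnibus$p_adjusted >= out$omnibus$p_value))
  expect_equal(nrow(out$post_hoc), 9 * 3)
  # two-group tables fall back to Mann-Whitney with no post hoc
  two <- cohort[cohort$group != "HB", ]
  out2 <- compare_feature_groups(two)
  expect_true(all(out2$omnibus$method == "Mann-Whitney U"))
  expect_equal(nrow(out2$post_hoc), 0)
  rt <- roc_table(cohort, positive = "NB", negative = "W")
  expect_equal(nrow(rt), 9)
  expect_true(all(rt$auc >= 0 & rt$auc <= 1))
  expect_true(all(rt$ci_low <= rt$auc & rt$auc <= rt$ci_high))
})
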