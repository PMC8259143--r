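test_that("Pearson chi-square reproduces cohort contingency statistics", {
  # gender x diagnosis counts from the reference cohort
  res <- pearson_chi_square(matrix(c(48, 7, 26, 24), 2, 2), "gender")
  expect_lt(abs(res$statistic - 15.661), 0.02)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)
  # perfectly independent table
  expect_equal(pearson_chi_square(matrix(10, 2, 2))$statistic, 0)
  # symmetry under transposition and row/column permutation
  m <- matrix(c(9, 65, 13, 18), 2, 2)
  s0 <- pearson_chi_square(m)$statistic
  expect_equal(pearson_chi_square(t(m))$statistic, s0)
  expect_equal(pearson_chi_square(m[2:1, ])$statistic, s0)
  expect_equal(pearson_chi_square(m[, 2:1])$statistic, s0)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 6), 2, 2)), "zero")
  expect_error(pearson_chi_square(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("pooled t from summaries equals the raw-sample path exactly", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(30 + i, 10, 3); y <- rnorm(20, 12, 2)
    a <- pooled_t_test(x, y)
    b <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$statistic, unname(b$statistic))
    expect_equal(a$df, unname(b$parameter))
    expect_equal(a$p_value, b$p.value)
  }
  expect_equal(pooled_t_from_summary(5, 2, 10, 5, 3, 12)$statistic, 0)
  expect_error(pooled_t_from_summary(1, 1, 1, 2, 1, 5), ">= 2")
  expect_error(pooled_t_from_summary(1, 0, 10, 2, 1, 5), "> 0")
})

test_that("Mann-Whitney Z behaves at its closed-form extremes", {
  # identical samples: perfectly balanced ranks, Z = 0
  x <- c(1, 2, 3, 4)
  res <- mann_whitney_z(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$groups$U, length(x)^2 / 2)
  # complete separation: U attains n1*n2 and Z its no-tie maximum
  y <- 1:6; z <- 7:11
  res2 <- mann_whitney_z(z, y)
  n1 <- 5; n2 <- 6; N <- 11
  expect_equal(res2$groups$U, n1 * n2)
  zmax <- (n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(res2$statistic, zmax)
  expect_error(mann_whitney_z(c(2, 2), c(2, 2)), "tied")
})

test_that("exact Mann-Whitney p matches the permutation distribution", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(4)          # no ties, enumerable
    mine <- mann_whitney_z(x, y, exact = TRUE)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$groups$p_exact, ref$p.value)
  }
})

test_that("normality screen holds its level and detects skew", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(100))$is_normal
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(1)
  expect_false(ks_normality(exp(rnorm(200)))$is_normal)
  expect_error(ks_normality(rep(3, 10)), "variance")
  expect_error(ks_normality(c(1, 2)), "at least 4")
})

test_that("group comparison dispatches on variable type and normality", {
  tab <- fixture_cohort
  expect_equal(compare_groups(tab, "gender")$test, "chi-square")
  expect_equal(compare_groups(tab, "pseudocapsule")$test, "chi-square")
  expect_equal(compare_groups(tab, "AVT_PCP_1")$test, "pooled-t")
  skewed <- tab
  set.seed(9)
  skewed$AVT_PCP_1 <- exp(rnorm(nrow(tab), 0, 1))
  expect_equal(compare_groups(skewed, "AVT_PCP_1")$test, "mann-whitney")
  expect_error(compare_groups(tab, "not_a_column"), "not in table")
  one <- tab[tab$class == "ccRCC", ]
  expect_error(compare_groups(one, "AVT_PCP_1"), "both lesion classes")
})

test_that("dispatch pipeline holds its type-I error on null cohorts", {
  rej <- vapply(1:1000, function(s) {
    set.seed(s)
    tab <- data.frame(class = rep(c("ccRCC", "AML.wovf"), c(74, 31)),
                      v = rnorm(105))
    compare_groups(tab, "v")$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("ICC is the two-way random absolute-agreement single-measure form", {
  m <- cbind(a = c(10, 20, 30, 40, 55), b = c(10, 20, 30, 40, 55))
  expect_equal(icc_agreement(m), 1)
  # observer noise with variance equal to the between-lesion variance
  # halves the agreement
  set.seed(3)
  truth <- rnorm(4000, 0, 1)
  m2 <- cbind(truth + rnorm(4000), truth + rnorm(4000))
  expect_lt(abs(icc_agreement(m2) - 0.5), 0.05)
  expect_error(icc_agreement(m[, 1, drop = FALSE]), "2 observers")
  expect_error(icc_agreement(m[1:2, ]), "3 lesions")
})

test_that("ICC agrees with an independent mixed-model estimate", {
  skip_if_not_installed("lme4")
  set.seed(11)
  truth <- rnorm(60, 100, 20)
  m <- cbind(truth + rnorm(60, 1, 8), truth + rnorm(60, -1, 8),
             truth + rnorm(60, 0, 8))
  d <- data.frame(y = as.vector(m),
                  lesion = factor(rep(seq_len(60), 3)),
                  obs = factor(rep(1:3, each = 60)))
  fit <- lme4::lmer(y ~ (1 | lesion) + (1 | obs), data = d)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc_lmm <- vc$vcov[vc$grp == "lesion"] / sum(vc$vcov)
  expect_lt(abs(icc_agreement(m) - icc_lmm), 0.02)
})

test_that("rank AUC equals all-pairs counting and the U statistic", {
  scores <- c(1, 2, 3, 4); labels <- c(0, 0, 1, 1)
  r <- roc_auc(scores, labels, positive_class = 1)
  # brute force over the 2 x 2 score pairs
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- expand.grid(p = pos, n = neg)
  brute <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
  expect_equal(r$auc, brute)
  # AUC = U / (n1 n2) identity
  set.seed(21)
  x <- rnorm(40, 1); y <- rnorm(25)
  u <- mann_whitney_z(x, y)$groups$U
  r2 <- roc_auc(c(x, y), rep(c("ccRCC", "AML.wovf"), c(40, 25)),
                direction = ">")
  expect_equal(r2$auc, u / (40 * 25))
  # extremes
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0), 1)$auc, 1)
  set.seed(2)
  r3 <- roc_auc(rnorm(4000), rep(c(1, 0), 2000), 1)
  expect_lt(abs(r3$auc - 0.5), 0.05)
  expect_error(roc_auc(1:4, rep(1, 4), 1), "both classes")
})

test_that("AUC and its CI match an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(rnorm(74, 1), rnorm(31))
  labels <- rep(c("ccRCC", "AML.wovf"), c(74, 31))
  mine <- roc_auc(scores, labels)
  ref <- pROC::auc(pROC::roc(labels, scores, levels = c("AML.wovf",
                                                        "ccRCC"),
                             direction = "<", quiet = TRUE))
  expect_equal(mine$auc, as.numeric(ref), tolerance = 1e-12)
  expect_true(mine$ci[1] >= 0 && mine$ci[2] <= 1)
  expect_true(mine$ci[1] <= mine$auc && mine$auc <= mine$ci[2])
})
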