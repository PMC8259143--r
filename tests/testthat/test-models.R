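test_that("published models carry the fixed printed coefficients", {
  m <- published_model("CMP")
  expect_s3_class(m, "ct_logit")
  expect_equal(m$intercept, -35.318)
  expect_equal(unname(m$coefficients["gender"]), 6.796)
  expect_equal(unname(m$coefficients["RER_CMP_2"]), 0.185)
  expect_equal(m$threshold, 0.5)
  p <- published_model("PCP")
  expect_equal(p$intercept, 5.257)
  expect_equal(unname(p$coefficients["AVT_PCP_1"]), -0.215)
  # one model per phase, four terms each
  for (ph in c("PCP", "CMP", "NP", "EP"))
    expect_equal(nrow(published_model(ph)$inference), 4)
  expect_error(published_model("XX"), "unknown phase")
})

test_that("probability prediction is the logistic link over the linear predictor", {
  m <- published_model("CMP")
  m$intercept <- 0
  m$coefficients[] <- 0
  expect_equal(predict_probability(m, data.frame(gender = "male",
                                                 cystic = 0,
                                                 RER_CMP_2 = 1,
                                                 SHR_CMP = 1)), 0.5)
  m2 <- published_model("CMP")
  row <- data.frame(gender = "female", cystic = 1, RER_CMP_2 = 100,
                    SHR_CMP = 300)
  eta <- -35.318 + 3.361 + 0.185 * 100 + 0.038 * 300
  expect_equal(predict_probability(m2, row), plogis(eta))
  # gender accepted as label or as 0/1 coding
  row2 <- row; row2$gender <- 0
  expect_equal(predict_probability(m2, row2), predict_probability(m2, row))
  expect_error(predict_probability(m2, data.frame(gender = "male")),
               "missing variable")
  expect_equal(predict(m2, row, type = "class"),
               ifelse(plogis(eta) >= 0.5, "ccRCC", "AML.wovf"))
})

test_that("worked corticomedullary lesions are classified correctly", {
  m <- published_model("CMP")
  # ccRCC lesion: male, cystic degeneration assumed absent
  p_cc <- predict_probability(m, data.frame(gender = "male", cystic = 0,
                                            RER_CMP_2 = 115.76,
                                            SHR_CMP = 369.35))
  p_aml <- predict_probability(m, data.frame(gender = "male", cystic = 0,
                                             RER_CMP_2 = 96.08,
                                             SHR_CMP = 223.46))
  expect_gt(p_cc, 0.99)
  expect_lt(p_aml, 0.15)
  expect_gt(p_cc, m$threshold)
  expect_lt(p_aml, m$threshold)
})

test_that("performance metrics are exact count ratios", {
  pf <- performance_from_counts(69, 5, 20, 11)
  expect_identical(pf$sensitivity, 69 / 74)
  expect_identical(pf$specificity, 20 / 31)
  expect_identical(pf$ppv, 69 / 80)
  expect_identical(pf$npv, 20 / 25)
  expect_identical(pf$accuracy, 89 / 105)
  expect_equal(sum(pf$counts), 105)
})

test_that("model evaluation tabulates the confusion at the threshold", {
  set.seed(31)
  tab <- simulate_cohort(cohort_config(seed = 31))
  pf <- evaluate_model(published_model("CMP"), tab)
  expect_equal(sum(pf$counts), nrow(tab))
  expect_equal(pf$sensitivity,
               unname(pf$counts["TP"] / (pf$counts["TP"] + pf$counts["FN"])))
  expect_gt(pf$auc$auc, 0.5)
  # a degenerate always-positive model: sensitivity 1, specificity 0
  m <- published_model("CMP"); m$intercept <- 1e6
  pf2 <- evaluate_model(m, tab)
  expect_equal(pf2$sensitivity, 1)
  expect_equal(pf2$specificity, 0)
  # a perfect separator scores every rate 1
  toy <- data.frame(class = rep(c("ccRCC", "AML.wovf"), each = 10),
                    gender = "male", cystic = 0,
                    RER_CMP_2 = rep(c(500, -500), each = 10), SHR_CMP = 0)
  m3 <- published_model("CMP"); m3$intercept <- 0
  m3$coefficients[] <- c(0, 0, 1, 0)
  pf3 <- evaluate_model(m3, toy)
  expect_equal(pf3$accuracy, 1)
  expect_equal(pf3$auc$auc, 1)
  expect_error(evaluate_model(m3, toy[0, ]), "empty")
})

test_that("logistic refits recover known generating coefficients", {
  set.seed(17)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.5 + 1.2 * x1 - 0.8 * x2
  tab <- data.frame(class = ifelse(rbinom(n, 1, plogis(eta)) == 1,
                                   "ccRCC", "AML.wovf"),
                    f1 = x1, f2 = x2)
  fit <- fit_logistic(tab, c("f1", "f2"))
  expect_lt(abs(fit$coefficients["f1"] - 1.2) / 1.2, 0.1)
  expect_lt(abs(fit$coefficients["f2"] + 0.8) / 0.8, 0.1)
  expect_true(all(c("odds_ratio", "ci_lower", "ci_upper", "p_value") %in%
                    names(fit$inference)))
})

test_that("a single binary predictor reproduces the cross-product odds ratio", {
  tab <- data.frame(
    class = rep(c("ccRCC", "ccRCC", "AML.wovf", "AML.wovf"),
                c(48, 26, 7, 24)),
    gender = rep(c("male", "female", "male", "female"), c(48, 26, 7, 24)))
  fit <- fit_logistic(tab, "gender")
  expect_equal(unname(exp(fit$coefficients["gender"])),
               (48 * 24) / (26 * 7), tolerance = 1e-6)
})

test_that("complete separation raises an explicit diagnostic", {
  tab <- data.frame(class = rep(c("ccRCC", "AML.wovf"), each = 15),
                    f = c(rnorm(15, 10), rnorm(15, -10)))
  expect_warning(fit_logistic(tab, "f"), class = "separation")
})

test_that("backward screening keeps true effects and drops noise", {
  # with 4 noise candidates and per-variable retention level 0.05, the
  # chance of at least one surviving noise variable is ~1 - 0.95^4, so the
  # exact-set recovery rate sits near 0.8; the true effects themselves are
  # never eliminated at this effect size and n
  set.seed(19)
  sel <- replicate(50, {
    n <- 1000
    x <- matrix(rnorm(n * 6), n, 6)
    colnames(x) <- paste0("v", 1:6)
    eta <- -0.3 + 1.0 * x[, 1] - 0.9 * x[, 4]
    tab <- data.frame(class = ifelse(rbinom(n, 1, plogis(eta)) == 1,
                                     "ccRCC", "AML.wovf"), x)
    screen_variables(tab, paste0("v", 1:6))$selected
  }, simplify = FALSE)
  true_kept <- vapply(sel, function(s) all(c("v1", "v4") %in% s),
                      logical(1))
  exact <- vapply(sel, function(s) setequal(s, c("v1", "v4")), logical(1))
  expect_equal(mean(true_kept), 1)
  expect_gte(mean(exact), 0.7)
})

test_that("screening pure noise usually returns an empty selection", {
  set.seed(23)
  empty <- replicate(60, {
    n <- 400
    x <- matrix(rnorm(n * 3), n, 3)
    colnames(x) <- paste0("v", 1:3)
    tab <- data.frame(class = rep(c("ccRCC", "AML.wovf"), length.out = n),
                      x)
    length(screen_variables(tab, paste0("v", 1:3))$selected) == 0
  })
  expect_gte(mean(empty), 0.8)
  # a single strong effect is retained
  set.seed(8)
  n <- 500
  x <- rnorm(n)
  tab <- data.frame(class = ifelse(rbinom(n, 1, plogis(2 * x)) == 1,
                                   "ccRCC", "AML.wovf"), v = x)
  expect_equal(screen_variables(tab, "v")$selected, "v")
})

test_that("refit corticomedullary model outperforms the pre-contrast model", {
  aucs <- vapply(1:40, function(s) {
    tab <- simulate_cohort(cohort_config(seed = 4000 + s))
    mc <- suppressWarnings(fit_logistic(tab, published_vars$CMP, "CMP"))
    mp <- suppressWarnings(fit_logistic(tab, published_vars$PCP, "PCP"))
    c(evaluate_model(mc, tab)$auc$auc, evaluate_model(mp, tab)$auc$auc)
  }, numeric(2))
  expect_gt(mean(aucs[1, ]), mean(aucs[2, ]))
})
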