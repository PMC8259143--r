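## ---- two-group comparison suite, ICC and ROC ----------------------------

comparison_result <- function(variable, test, statistic, df = NA_real_,
                              p_value, groups = NULL) {
  structure(list(variable = variable, test = test,
                 statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), groups = groups),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.3f%s, p = %.4g\n", x$variable, x$test,
              x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %g)", x$df),
              x$p_value))
  invisible(x)
}

#' Pearson chi-square test for a contingency table
#'
#' Pearson statistic without continuity correction (the convention that
#' reproduces standard statistical-package output for 2 x 2 cohort tables).
#'
#' @param counts matrix of non-negative integer counts (no zero margin).
#' @param variable label carried into the result.
#' @return A `comparison_result`.
#' @export
#' @examples
#' pearson_chi_square(matrix(c(48, 7, 26, 24), 2, 2))
pearson_chi_square <- function(counts, variable = "categorical") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column total", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  comparison_result(variable, "chi-square", ct$statistic,
                    ct$parameter, ct$p.value,
                    groups = list(counts = counts))
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance (pooled) independent-samples t from group means, SDs and
#' sizes, df = n1 + n2 - 2.  This is the form needed to re-derive published
#' group comparisons from reported means +/- SDs.
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs (> 0) and sizes (>= 2).
#' @param variable label carried into the result.
#' @return A `comparison_result` with per-group summaries.
#' @export
#' @examples
#' pooled_t_from_summary(32.78, 6.50, 74, 38.33, 5.47, 31)
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                  variable = "quantitative") {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (s1 <= 0 || s2 <= 0) stop("group SDs must be > 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  comparison_result(variable, "pooled-t", t, df, 2 * pt(-abs(t), df),
                    groups = list(g1 = c(mean = m1, sd = s1, n = n1),
                                  g2 = c(mean = m2, sd = s2, n = n2)))
}

#' Pooled two-sample t test from raw samples
#'
#' Wrapper around [pooled_t_from_summary()] computing the group summaries
#' from the data; numerically identical to `t.test(..., var.equal = TRUE)`.
#'
#' @param x,y numeric samples.
#' @param variable label.
#' @return A `comparison_result`.
#' @export
pooled_t_test <- function(x, y, variable = "quantitative") {
  pooled_t_from_summary(mean(x), sd(x), length(x),
                        mean(y), sd(y), length(y), variable)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Computes the U statistic and its standardized Z with the tie-corrected
#' variance (the asymptotic Z printed by mainstream statistics packages; no
#' continuity correction), plus a two-sided p value.  For small samples an
#' exact permutation p value over all rank assignments can be requested.
#'
#' @param x,y non-empty numeric samples.
#' @param variable label.
#' @param exact also compute the exact permutation p value (feasible for
#'   `choose(n1 + n2, n1)` up to ~1e5).
#' @return A `comparison_result`; `statistic` is Z, with `U` and optionally
#'   `p_exact` in `$groups`.
#' @export
mann_whitney_z <- function(x, y, variable = "quantitative", exact = FALSE) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L)
    stop("all values tied across both samples", call. = FALSE)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(all_v)
  sig2 <- n1 * n2 / 12 * ((N^3 - N - sum(ties^3 - ties)) / (N * (N - 1)))
  z <- (U - mu) / sqrt(sig2)
  res <- comparison_result(variable, "mann-whitney", z, NA_real_,
                           2 * pnorm(-abs(z)),
                           groups = list(U = U, n1 = n1, n2 = n2))
  if (exact) {
    idx <- combn(N, n1)
    Us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    dev <- abs(Us - mu)
    res$groups$p_exact <- mean(dev >= abs(U - mu) - 1e-9)
  }
  res
}

#' Normality screen (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' KS test against a normal distribution with estimated mean and SD
#' (Lilliefors correction), as applied by common statistical packages when
#' asked for a "Kolmogorov-Smirnov normality test".  The resulting flag
#' drives the t-versus-Mann-Whitney dispatch in [compare_groups()].
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @param alpha significance level for the `is_normal` flag.
#' @return List: `statistic`, `p_value`, `is_normal`.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (sd(x) == 0) stop("zero-variance sample", call. = FALSE)
  lt <- nortest::lillie.test(x)
  list(statistic = unname(lt$statistic), p_value = lt$p.value,
       is_normal = lt$p.value >= alpha)
}

#' Compare one variable between the two lesion classes
#'
#' Dispatch rule: categorical variables (character, factor, or numeric with
#' at most two distinct values) get the Pearson chi-square; quantitative
#' variables get the pooled t test when both class samples pass the
#' normality screen, and the Mann-Whitney U test otherwise.
#'
#' @param table lesion table with a `class` column holding both classes.
#' @param variable column name to compare.
#' @param alpha normality-screen level.
#' @return A `comparison_result`.
#' @export
compare_groups <- function(table, variable, alpha = 0.05) {
  if (!variable %in% names(table))
    stop(sprintf("variable '%s' not in table", variable), call. = FALSE)
  cl <- table$class
  if (length(unique(cl)) < 2)
    stop("both lesion classes must be present", call. = FALSE)
  v <- table[[variable]]
  categorical <- is.character(v) || is.factor(v) ||
    length(unique(na.omit(v))) <= 2
  if (categorical) {
    counts <- t(as.matrix(table(factor(v), factor(cl, levels = .classes))))
    res <- pearson_chi_square(counts, variable)
    res$groups$dispatch <- "categorical -> chi-square"
    return(res)
  }
  g1 <- v[cl == .classes[1]]; g2 <- v[cl == .classes[2]]
  if (length(g1) < 4 || length(g2) < 4) {
    res <- mann_whitney_z(g1, g2, variable)
    res$groups$dispatch <- "group too small for normality screen -> mann-whitney"
    return(res)
  }
  norm1 <- ks_normality(g1, alpha)$is_normal
  norm2 <- ks_normality(g2, alpha)$is_normal
  if (norm1 && norm2) {
    res <- pooled_t_test(g1, g2, variable)
    res$groups$dispatch <- "both normal -> pooled-t"
  } else {
    res <- mann_whitney_z(g1, g2, variable)
    res$groups$dispatch <- "non-normal -> mann-whitney"
  }
  res
}

#' Inter-observer agreement ICC
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation (ICC(2,1)), from the mean squares of the lesion x observer
#' layout.
#'
#' @param measurements numeric matrix or data.frame, rows = lesions (>= 3),
#'   columns = observers (>= 2); no missing cells.
#' @return The ICC value.
#' @export
#' @examples
#' m <- cbind(obs1 = c(10, 20, 30, 40), obs2 = c(11, 19, 32, 38))
#' icc_agreement(m)
icc_agreement <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("need at least 2 observers", call. = FALSE)
  if (n < 3) stop("need at least 3 lesions", call. = FALSE)
  if (anyNA(m)) stop("missing cells are not supported", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Nonparametric ROC AUC with Hanley-McNeil confidence interval
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling, oriented so that
#' higher scores indicate the positive class; with `direction = "auto"` the
#' orientation is flipped when needed so the reported AUC is >= 0.5, and the
#' flip is recorded.  The 95% CI uses the Hanley-McNeil standard error,
#' clipped to [0, 1].
#'
#' @param scores numeric scores.
#' @param labels class labels (both classes present).
#' @param positive_class label counted as positive (default `"ccRCC"`).
#' @param direction `">"` (higher score = positive), `"<"`, or `"auto"`.
#' @param conf_level confidence level.
#' @return List of class `roc_result`: `auc`, `ci`, `se`, `positive_class`,
#'   `direction`, `flipped`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive_class = "ccRCC",
                    direction = c("auto", ">", "<"), conf_level = 0.95) {
  direction <- match.arg(direction)
  pos <- labels == positive_class
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  flipped <- FALSE
  if (direction == "<" || (direction == "auto" && auc < 0.5)) {
    auc <- 1 - auc
    flipped <- direction != "<"
  }
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zq * se, 0), 1)
  structure(list(auc = auc, ci = ci, se = se,
                 positive_class = positive_class,
                 direction = if (direction == "auto") ">" else direction,
                 flipped = flipped, n_pos = n1, n_neg = n2),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), positive = %s%s\n",
              x$auc, x$ci[1], x$ci[2], x$positive_class,
              if (x$flipped) " [orientation flipped]" else ""))
  invisible(x)
}
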