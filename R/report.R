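## ---- cohort-level report builders ----------------------------------------

comparison_row <- function(res) {
  data.frame(variable = res$variable, test = res$test,
             statistic = res$statistic, df = res$df,
             p_value = res$p_value, stringsAsFactors = FALSE)
}

#' Demographic / morphology comparison report
#'
#' Compares gender, location, growth pattern, pseudocapsule sign, cystic
#' degeneration and angular interface (chi-square) and age and size
#' (normality-dispatched t / Mann-Whitney) between the two classes.
#'
#' @param table lesion table.
#' @return data.frame, one row per variable; the dispatch decisions are
#'   attached as attribute `"log"`.
#' @export
report_demographics <- function(table) {
  vars <- intersect(c("gender", "location", "growth", "pseudocapsule",
                      "cystic", "angular", "age", "size_cm"), names(table))
  if (!length(vars))
    return(data.frame(variable = character(), test = character(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric()))
  log <- character()
  rows <- lapply(vars, function(v) {
    res <- tryCatch(compare_groups(table, v), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v, test = NA, statistic = NA, df = NA,
                        p_value = NA))
    log <<- c(log, sprintf("%s: %s", v, res$groups$dispatch))
    comparison_row(res)
  })
  out <- do.call(rbind, rows)
  attr(out, "log") <- log
  out
}

#' Quantitative parameter comparison report
#'
#' Runs the normality-dispatched two-group comparison for every
#' quantitative CT parameter present in the table, with per-class
#' means +/- SDs.
#'
#' @param table lesion table.
#' @return data.frame with per-class summaries, test, statistic and p; the
#'   dispatch log is attached as attribute `"log"`.
#' @export
report_quantitative <- function(table) {
  feats <- intersect(setdiff(quant_feature_names(), c("age", "size_cm")),
                     names(table))
  log <- character()
  rows <- lapply(feats, function(v) {
    g1 <- table[[v]][table$class == .classes[1]]
    g2 <- table[[v]][table$class == .classes[2]]
    res <- tryCatch(compare_groups(table, v), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v, mean_ccrcc = mean(g1),
                        sd_ccrcc = sd(g1), mean_aml = mean(g2),
                        sd_aml = sd(g2), test = NA, statistic = NA,
                        p_value = NA))
    log <<- c(log, sprintf("%s: %s", v, res$groups$dispatch))
    data.frame(variable = v, mean_ccrcc = mean(g1), sd_ccrcc = sd(g1),
               mean_aml = mean(g2), sd_aml = sd(g2), test = res$test,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "log") <- log
  out
}

#' ROC report for discriminative quantitative parameters
#'
#' Computes the nonparametric AUC with Hanley-McNeil 95% CI for every
#' quantitative parameter whose two-group comparison is significant at
#' `alpha`.
#'
#' @param table lesion table.
#' @param alpha significance filter on the group comparison.
#' @return data.frame: variable, auc, ci_lower, ci_upper.
#' @export
report_roc <- function(table, alpha = 0.05) {
  q <- report_quantitative(table)
  keep <- q$variable[!is.na(q$p_value) & q$p_value < alpha]
  rows <- lapply(keep, function(v) {
    r <- roc_auc(table[[v]], table$class, "ccRCC")
    data.frame(variable = v, auc = r$auc, ci_lower = r$ci[1],
               ci_upper = r$ci[2], stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(variable = character(), auc = numeric(),
                      ci_lower = numeric(), ci_upper = numeric()))
  do.call(rbind, rows)
}

#' Model performance report across phases
#'
#' Evaluates the published per-phase models (or freshly screened refits) on
#' a lesion table.
#'
#' @param table lesion table.
#' @param refit screen and refit per phase instead of scoring the published
#'   coefficients.
#' @return List with `performance` (data.frame across phases) and `models`
#'   (the `ct_logit` objects).
#' @export
report_models <- function(table, refit = FALSE) {
  models <- lapply(.phases, function(ph) {
    if (refit) {
      cand <- phase_candidates(ph, table)
      sel <- screen_variables(table, cand, ph)
      sel$model
    } else published_model(ph)
  })
  names(models) <- .phases
  perf <- lapply(.phases, function(ph) {
    m <- models[[ph]]
    if (is.null(m)) return(NULL)
    pf <- tryCatch(evaluate_model(m, table), error = function(e) NULL)
    if (is.null(pf)) return(NULL)
    data.frame(phase = ph, sensitivity = pf$sensitivity,
               specificity = pf$specificity, ppv = pf$ppv, npv = pf$npv,
               accuracy = pf$accuracy, auc = pf$auc$auc,
               auc_lower = pf$auc$ci[1], auc_upper = pf$auc$ci[2],
               stringsAsFactors = FALSE)
  })
  list(performance = do.call(rbind, perf), models = models)
}
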