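## ---- per-phase logistic prediction models (ct_logit S3 class) -----------

new_ct_logit <- function(phase, intercept, coefficients, threshold = 0.5,
                         inference = NULL, source = "fitted", fit = NULL) {
  structure(list(phase = phase, intercept = unname(intercept),
                 coefficients = coefficients, threshold = threshold,
                 coding = list(gender = c(male = 1, female = 0),
                               flags = c(present = 1, absent = 0),
                               class = c(ccRCC = 1, AML.wovf = 0)),
                 inference = inference, source = source, fit = fit),
            class = "ct_logit")
}

#' Published per-phase logistic prediction model
#'
#' Returns the fixed, published logistic model for one scanning phase as a
#' `ct_logit` object.  Coding: male = 1, morphology-flag present = 1,
#' ccRCC = 1; classification threshold 0.5.  The four models combine gender
#' and a morphology flag with the phase's quantitative parameters
#' (pre-contrast: small-ROI attenuation; enhanced phases: smaller-ROI
#' relative enhancement ratio plus a heterogeneity parameter).
#'
#' @param phase one of `"PCP"`, `"CMP"`, `"NP"`, `"EP"`.
#' @return A `ct_logit` with the exact published intercept and coefficients;
#'   the published odds ratios, CIs and p values are in `$inference`.
#' @export
#' @examples
#' published_model("CMP")
published_model <- function(phase) {
  if (length(phase) != 1L || !phase %in% .phases)
    stop(sprintf("unknown phase '%s' (use PCP, CMP, NP or EP)",
                 paste(phase, collapse = ",")), call. = FALSE)
  res <- published_models_resource()
  m <- res$models[[phase]]
  terms <- do.call(rbind, lapply(m$terms, as.data.frame))
  new_ct_logit(phase, m$intercept,
               setNames(terms$coef, terms$term),
               threshold = res$threshold,
               inference = data.frame(
                 term = terms$term, coef = terms$coef,
                 odds_ratio = terms$or, ci_lower = terms$ci_lower,
                 ci_upper = terms$ci_upper, p_value = terms$p,
                 stringsAsFactors = FALSE),
               source = "published")
}

published_models_resource <- function() {
  path <- system.file("extdata", "published_models.json",
                      package = "renalroi")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Consistency of published coefficients and odds ratios
#'
#' For every term of the four published models, compares `exp(coefficient)`
#' with the printed odds ratio.  Because coefficients are printed to three
#' decimals, consistent rows agree to a fraction of a percent; larger
#' discrepancies indicate typos in the printed odds-ratio column (the
#' coefficients, which also match the geometric centres of the printed Wald
#' CIs, are taken as authoritative).
#'
#' @return data.frame: `phase`, `term`, `coef`, `or_printed`,
#'   `or_from_coef`, `rel_err`.
#' @export
odds_ratio_consistency <- function() {
  out <- do.call(rbind, lapply(.phases, function(ph) {
    inf <- published_model(ph)$inference
    data.frame(phase = ph, term = inf$term, coef = inf$coef,
               or_printed = inf$odds_ratio,
               or_from_coef = exp(inf$coef),
               rel_err = abs(exp(inf$coef) - inf$odds_ratio) /
                 inf$odds_ratio,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## numeric design vector/matrix for a model's variables, applying the coding
resolve_variables <- function(table, vars) {
  miss <- setdiff(vars, names(table))
  if (length(miss))
    stop(sprintf("missing variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  x <- sapply(vars, function(v) {
    col <- table[[v]]
    if (v == "gender" && !is.numeric(col))
      as.numeric(col == "male")
    else as.numeric(col)
  })
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(table))
  colnames(x) <- vars
  x
}

#' Predicted probability of ccRCC for lesion rows
#'
#' Evaluates the logistic link over the model's linear predictor,
#' `plogis(intercept + sum(coef * value))`, with gender coded male = 1 and
#' morphology flags coded present = 1.
#'
#' @param model a `ct_logit`.
#' @param lesion_row data.frame row(s) holding every model variable.
#' @return Probability vector.
#' @export
#' @examples
#' m <- published_model("CMP")
#' predict_probability(m, data.frame(gender = "male", cystic = 0,
#'                                   RER_CMP_2 = 115.76, SHR_CMP = 369.35))
predict_probability <- function(model, lesion_row) {
  stopifnot(inherits(model, "ct_logit"))
  x <- resolve_variables(as.data.frame(lesion_row),
                         names(model$coefficients))
  eta <- model$intercept + drop(x %*% model$coefficients)
  stats::plogis(eta)
}

#' @export
predict.ct_logit <- function(object, newdata,
                             type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  p <- predict_probability(object, newdata)
  switch(type,
         response = p,
         link = stats::qlogis(p),
         class = ifelse(p >= object$threshold, "ccRCC", "AML.wovf"))
}

#' @export
coef.ct_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.ct_logit <- function(x, ...) {
  cat(sprintf("Per-phase logistic prediction model (%s, %s)\n", x$phase,
              x$source))
  print(round(coef(x), 4))
  cat(sprintf("threshold %.2f; coding: male = 1, flag present = 1, ccRCC = 1\n",
              x$threshold))
  invisible(x)
}

#' @export
summary.ct_logit <- function(object, ...) {
  cat(sprintf("Phase %s model (%s)\n", object$phase, object$source))
  if (!is.null(object$inference)) {
    inf <- object$inference
    inf$odds_ratio <- round(inf$odds_ratio, 3)
    print(inf, row.names = FALSE)
  } else {
    print(round(coef(object), 4))
  }
  invisible(object)
}

#' Classification performance from confusion counts
#'
#' All six performance metrics as exact ratios of their integer counts
#' (ccRCC positive): sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV
#' TP/(TP+FP), NPV TN/(TN+FN), accuracy (TP+TN)/N.
#'
#' @param tp,fn,tn,fp non-negative integer confusion counts.
#' @param auc optional `roc_result` to attach.
#' @return List of class `ct_performance`.
#' @export
#' @examples
#' performance_from_counts(69, 5, 20, 11)
performance_from_counts <- function(tp, fn, tn, fp, auc = NULL) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(
    counts = c(TP = tp, FN = fn, TN = tn, FP = fp),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    auc = auc), class = "ct_performance")
}

#' @export
print.ct_performance <- function(x, ...) {
  co <- x$counts
  fmt <- function(v, num, den) sprintf("%.3f (%d/%d)", v, num, den)
  cat("Sensitivity ", fmt(x$sensitivity, co["TP"], co["TP"] + co["FN"]), "\n",
      "Specificity ", fmt(x$specificity, co["TN"], co["TN"] + co["FP"]), "\n",
      "PPV         ", fmt(x$ppv, co["TP"], co["TP"] + co["FP"]), "\n",
      "NPV         ", fmt(x$npv, co["TN"], co["TN"] + co["FN"]), "\n",
      "Accuracy    ", fmt(x$accuracy, co["TP"] + co["TN"], sum(co)), "\n",
      sep = "")
  if (!is.null(x$auc))
    cat(sprintf("AUC         %.3f (95%% CI %.3f-%.3f)\n", x$auc$auc,
                x$auc$ci[1], x$auc$ci[2]))
  invisible(x)
}

#' Evaluate a model on a lesion table
#'
#' Classifies every lesion at the model threshold (ccRCC positive),
#' tabulates the confusion counts, and computes sensitivity, specificity,
#' PPV, NPV, accuracy (each the exact ratio of its counts) and the
#' nonparametric AUC of the predicted probabilities.
#'
#' @param model a `ct_logit`.
#' @param table lesion table with `class` labels and all model variables.
#' @return A `ct_performance`.
#' @export
evaluate_model <- function(model, table) {
  if (!nrow(table)) stop("empty lesion table", call. = FALSE)
  p <- predict_probability(model, table)
  pred_pos <- p >= model$threshold
  obs_pos <- table$class == "ccRCC"
  performance_from_counts(sum(pred_pos & obs_pos),
                          sum(!pred_pos & obs_pos),
                          sum(!pred_pos & !obs_pos),
                          sum(pred_pos & !obs_pos),
                          auc = roc_auc(p, table$class, "ccRCC",
                                        direction = ">"))
}

#' Fit a per-phase logistic model by maximum likelihood
#'
#' Binomial GLM of ccRCC (coded 1) on the given variables with the package
#' coding (male = 1, flag present = 1), returning a `ct_logit` with
#' coefficients, odds ratios, Wald 95% CIs and p values.  Complete or
#' quasi-complete separation is reported through a `"separation"` warning
#' condition.
#'
#' @param table lesion table; at least 10 rows per class recommended.
#' @param variables character vector of predictor columns.
#' @param phase optional phase label attached to the model.
#' @param threshold classification threshold.
#' @return A `ct_logit`.
#' @export
fit_logistic <- function(table, variables, phase = NA_character_,
                         threshold = 0.5) {
  y <- as.numeric(table$class == "ccRCC")
  x <- resolve_variables(table, variables)
  dat <- data.frame(.y = y, x)
  colnames(dat) <- c(".y", variables)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", w$message))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || max(abs(coef(fit)[-1]), na.rm = TRUE) > 20)
    warning(structure(
      class = c("separation", "warning", "condition"),
      list(message = "complete or quasi-complete separation detected",
           call = sys.call(-1))))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  inf <- data.frame(term = variables, coef = unname(est[-1]),
                    odds_ratio = unname(exp(est[-1])),
                    ci_lower = unname(exp(est[-1] - 1.96 * se[-1])),
                    ci_upper = unname(exp(est[-1] + 1.96 * se[-1])),
                    p_value = unname(2 * pnorm(-abs(est[-1] / se[-1]))),
                    stringsAsFactors = FALSE)
  new_ct_logit(phase, est[1], est[-1], threshold, inf, "fitted", fit)
}

#' Backward variable screening by likelihood-ratio test
#'
#' Starting from the candidate set (in practice: the variables univariately
#' significant at the entry level), repeatedly drops the variable with the
#' largest likelihood-ratio p value above `alpha` and refits, until every
#' retained variable is significant.  An empty selection is a valid outcome
#' for pure-noise candidates.
#'
#' @param table lesion table.
#' @param candidate_vars character vector of candidate predictors.
#' @param phase optional phase label for the final model.
#' @param alpha retention level (default 0.05).
#' @return List: `selected` (character vector, possibly empty) and `model`
#'   (a `ct_logit`, or `NULL` when nothing is retained).
#' @export
screen_variables <- function(table, candidate_vars, phase = NA_character_,
                             alpha = 0.05) {
  vars <- candidate_vars
  model <- NULL
  while (length(vars)) {
    model <- suppressWarnings(fit_logistic(table, vars, phase))
    dr <- drop1(model$fit, test = "LRT")
    p <- dr[["Pr(>Chi)"]][-1]
    names(p) <- rownames(dr)[-1]
    worst <- which.max(p)
    if (length(worst) && p[worst] > alpha) {
      vars <- setdiff(vars, names(p)[worst])
      model <- NULL
    } else break
  }
  if (!length(vars)) return(list(selected = character(0), model = NULL))
  if (is.null(model))
    model <- suppressWarnings(fit_logistic(table, vars, phase))
  list(selected = vars, model = model)
}

#' Candidate variables for each phase's prediction model
#'
#' The demographic/morphology variables plus the phase's quantitative
#' parameters, the entry pool for [screen_variables()].
#'
#' @param phase scanning phase.
#' @param table optional lesion table; candidates are restricted to those
#'   univariately significant at `alpha` between the classes.
#' @param alpha univariate entry level.
#' @return Character vector of column names.
#' @export
phase_candidates <- function(phase, table = NULL, alpha = 0.05) {
  if (!phase %in% .phases) stop("unknown phase", call. = FALSE)
  base <- c("gender", "pseudocapsule", "cystic", "angular", "age",
            "size_cm")
  quant <- grep(paste0("_", phase, "(_|$)"), quant_feature_names(),
                value = TRUE)
  cand <- c(base, quant)
  if (is.null(table)) return(cand)
  keep <- vapply(cand, function(v) {
    res <- tryCatch(compare_groups(table, v, alpha),
                    error = function(e) NULL)
    !is.null(res) && res$p_value < alpha
  }, logical(1))
  cand[keep]
}
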