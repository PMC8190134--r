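#' Confusion counts (positive class = high risk)
#'
#' @param labels true labels, `"high"`/`"low"` (or 1/0).
#' @param predictions predicted labels, same coding.
#' @return list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) gf_data_error("labels and predictions differ in length")
  y <- as_binary(labels); p <- as_binary(predictions)
  list(tp = sum(y == 1 & p == 1), fn = sum(y == 1 & p == 0),
       fp = sum(y == 0 & p == 1), tn = sum(y == 0 & p == 0))
}

as_binary <- function(x) {
  if (is.character(x) || is.factor(x)) as.integer(as.character(x) == "high") else as.integer(x)
}

#' Classification rate panel from confusion counts
#'
#' Accuracy, sensitivity (high-risk recall), specificity (low-risk recall),
#' positive/negative predictive values, and positive/negative likelihood
#' ratios (`sens/(1-spec)` and `(1-sens)/spec`). Degenerate denominators are
#' flagged by the IEEE conventions rather than raising: `0/0` is `NaN` and a
#' positive likelihood ratio against zero false-positive rate is `Inf`.
#'
#' @param c confusion counts from [confusion()].
#' @return named list of the seven rates.
#' @export
rates <- function(c) {
  total <- c$tp + c$fn + c$fp + c$tn
  sens <- c$tp / (c$tp + c$fn)
  spec <- c$tn / (c$tn + c$fp)
  list(
    accuracy = (c$tp + c$tn) / total,
    sensitivity = sens,
    specificity = spec,
    ppv = c$tp / (c$tp + c$fp),
    npv = c$tn / (c$tn + c$fn),
    plr = sens / (1 - spec),
    nlr = (1 - sens) / spec
  )
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney identity (probability a random positive outscores
#' a random negative, ties counted one half), computed from mid-ranks; the
#' ROC points are the (FPR, TPR) pairs swept over every distinct score
#' threshold.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (`"high"`/`"low"` or 1/0); both classes
#'   required.
#' @return list with `auc` and a data frame `roc` (`threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(scores) != length(y)) gf_data_error("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) gf_data_error("both classes must be present to compute an ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
               data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  list(auc = auc, roc = roc)
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes,n counts.
#' @param level confidence level.
#' @return c(lower, upper), clipped to `[0, 1]`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n == 0) return(c(NaN, NaN))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  pmin(pmax(c(center - half, center + half), 0), 1)
}

# DeLong variance of the AUC via the structural components
# V10_i = mean_j psi(X_i, Y_j), V01_j = mean_i psi(X_i, Y_j),
# psi = 1, 1/2, 0 for X > Y, X == Y, X < Y.
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary(labels)
  x1 <- scores[y == 1]; x0 <- scores[y == 0]
  n1 <- length(x1); n0 <- length(x0)
  psi <- outer(x1, x0, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(s), 0), 1)
  list(auc = auc, ci = ci, var = s)
}

# Log-method CIs for likelihood ratios (Simel et al.): the log of the ratio
# is approximately normal with the usual counting-variance terms.
lr_ci <- function(c, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  sens <- c$tp / (c$tp + c$fn)
  spec <- c$tn / (c$tn + c$fp)
  plr <- sens / (1 - spec)
  nlr <- (1 - sens) / spec
  plr_ci <- nlr_ci <- c(NaN, NaN)
  if (c$tp > 0 && c$fp > 0) {
    se <- sqrt(1 / c$tp - 1 / (c$tp + c$fn) + 1 / c$fp - 1 / (c$fp + c$tn))
    plr_ci <- exp(log(plr) + c(-1, 1) * z * se)
  }
  if (c$fn > 0 && c$tn > 0) {
    se <- sqrt(1 / c$fn - 1 / (c$tp + c$fn) + 1 / c$tn - 1 / (c$fp + c$tn))
    nlr_ci <- exp(log(nlr) + c(-1, 1) * z * se)
  }
  list(plr = plr_ci, nlr = nlr_ci)
}

#' Confidence intervals for the metric panel
#'
#' Wilson score intervals for the proportion-type metrics (accuracy,
#' sensitivity, specificity, PPV, NPV), DeLong for the AUC, and the
#' log-method for the likelihood ratios. Degenerate cells yield `NaN` bounds.
#'
#' @param c confusion counts from [confusion()].
#' @param scores,labels held-out scores and labels (for the AUC interval).
#' @param level confidence level (default 0.95).
#' @return named list of `c(lower, upper)` intervals.
#' @export
confidence_intervals <- function(c, scores, labels, level = 0.95) {
  total <- c$tp + c$fn + c$fp + c$tn
  lr <- lr_ci(c, level)
  list(
    accuracy = wilson_ci(c$tp + c$tn, total, level),
    sensitivity = wilson_ci(c$tp, c$tp + c$fn, level),
    specificity = wilson_ci(c$tn, c$tn + c$fp, level),
    ppv = wilson_ci(c$tp, c$tp + c$fp, level),
    npv = wilson_ci(c$tn, c$tn + c$fn, level),
    plr = lr$plr,
    nlr = lr$nlr,
    auc = delong_ci(scores, labels, level)$ci
  )
}

#' Group descriptives with significance tests
#'
#' Per variable: mean and SD in the high- and low-risk groups, a two-sided
#' Welch t-test p-value for the group difference, and per-group Shapiro-Wilk
#' normality p-values (skipped with a flag for groups smaller than 3;
#' subsampled to 5000 for very large groups, the test's implementation limit).
#'
#' @param cohort data frame with `risk_label` and numeric variables.
#' @param variables columns to describe (default: all demographic and gait
#'   variables present).
#' @param alpha significance threshold for the `significant` flag.
#' @return data frame, one row per variable.
#' @export
group_descriptives <- function(cohort, variables = NULL, alpha = 0.05) {
  if (is.null(variables)) {
    candidates <- c(DEMO_FEATURES, gait_variable_names())
    variables <- intersect(candidates, names(cohort))
  }
  hi <- cohort$risk_label == "high"
  if (!any(hi) || all(hi)) gf_data_error("both risk groups must be non-empty")
  shapiro_p <- function(x) {
    if (length(x) < 3L) return(NA_real_)
    if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  welch_p <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  rows <- lapply(variables, function(v) {
    a <- cohort[[v]][hi]; b <- cohort[[v]][!hi]
    p <- welch_p(a, b)
    data.frame(variable = v,
               mean_high = mean(a), sd_high = stats::sd(a),
               mean_low = mean(b), sd_low = stats::sd(b),
               t_p = p,
               shapiro_p_high = shapiro_p(a), shapiro_p_low = shapiro_p(b),
               significant = is.finite(p) && p < alpha)
  })
  do.call(rbind, rows)
}

#' Full evaluation report for one per-speed model
#'
#' Assembles the complete panel on a held-out test set: confusion counts, the
#' seven rates, AUC, 95% confidence intervals for all of them, the ROC
#' points, the top-10 gain importance ranking, and group descriptives of the
#' test set. Deterministic given the model and data.
#'
#' @param model a [train_model()] result.
#' @param test held-out data frame with `risk_label` and the model features.
#' @param speed label recorded in the report (e.g. `"preferred"`).
#' @return a list of class `metrics_report`.
#' @export
full_report <- function(model, test, speed = "preferred") {
  pred <- predict_risk(model, test)
  cc <- confusion(test$risk_label, pred$label)
  rt <- rates(cc)
  ra <- roc_auc(pred$score, test$risk_label)
  ci <- confidence_intervals(cc, pred$score, test$risk_label)
  desc <- group_descriptives(test, variables = intersect(model$features, names(test)))
  structure(list(
    speed = speed, n_test = nrow(test), confusion = cc,
    metrics = c(rt, list(auc = ra$auc)), ci = ci, roc = ra$roc,
    importance = feature_importance_ranking(model, top_k = 10L, normalize = TRUE),
    descriptives = desc
  ), class = "metrics_report")
}

#' Serialize / load a metrics report as JSON
#'
#' @param report a [full_report()] result.
#' @param path JSON file path.
#' @return `write_report_json` returns `path` invisibly; `read_report_json`
#'   the report list.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  r$roc <- as.data.frame(r$roc)
  r$importance <- as.data.frame(r$importance)
  r$descriptives <- as.data.frame(r$descriptives)
  class(r) <- "metrics_report"
  r
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Fall-risk model report (%s speed), n_test = %d\n", x$speed, x$n_test))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)\n", x$metrics$auc, x$ci$auc[1], x$ci$auc[2]))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "plr", "nlr")) {
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n", m, x$metrics[[m]], x$ci[[m]][1], x$ci[[m]][2]))
  }
  cat("  top features:", paste(utils::head(x$importance$feature, 5), collapse = ", "), "\n")
  invisible(x)
}
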