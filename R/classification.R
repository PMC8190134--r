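#' Predictor set for a per-speed fall-risk model
#'
#' Each walking-speed model uses that speed's nine gait variables plus five
#' demographic covariates (age, sex, BMI, education level, total physical
#' activity). Cognition (MMSE) is not a predictor by default.
#'
#' @param speed `"slower"`, `"preferred"` or `"faster"`.
#' @return character vector of 14 column names.
#' @export
speed_feature_set <- function(speed) {
  speed <- match.arg(speed, GAIT_SPEEDS)
  c(paste(speed, GAIT_FEATURES, sep = "_"),
    "age", "sex", "bmi", "education_level", "pa_met_min_wk")
}

#' Model configuration
#'
#' Hyperparameters for the boosted-tree fall-risk classifier and the
#' evaluation protocol (70/30 stratified split, 10-fold cross-validation).
#' The boosting defaults (200 trees, learning rate 0.1, depth 3, gamma 0,
#' lambda 1) are conventional for tabular clinical data of this size.
#'
#' @param n_trees,learning_rate,max_depth,gamma,lambda,min_child_weight see
#'   [fit_gbt()].
#' @param train_fraction fraction of the cohort used for training.
#' @param cv_folds folds for cross-validated model selection.
#' @param threshold probability cut for the high-risk label.
#' @param seed integer seed for the split and fold assignment.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_trees = 200L, learning_rate = 0.1, max_depth = 3L,
                         gamma = 0, lambda = 1, min_child_weight = 1,
                         train_fraction = 0.7, cv_folds = 10L,
                         threshold = 0.5, seed = 1L) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    gf_param_error("train_fraction must lie strictly between 0 and 1")
  }
  if (!is_count(cv_folds, min = 2L)) gf_param_error("cv_folds must be an integer >= 2")
  if (gamma < 0 || lambda < 0) gf_param_error("penalties must be >= 0")
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), gamma = gamma, lambda = lambda,
                 min_child_weight = min_child_weight, train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), threshold = threshold,
                 seed = as.integer(seed)), class = "model_config")
}

#' Min-max scaler
#'
#' `minmax_scale_fit` learns per-feature training minima and maxima;
#' `minmax_scale_apply` maps features to `(x - min) / (max - min)`. Training
#' values land in `[0, 1]`; test values may fall outside (no clipping).
#' Constant features are flagged and mapped to 0.
#'
#' @param features numeric data frame or matrix (training set for `_fit`).
#' @return `minmax_scale_fit`: an object of class `minmax_scaler`;
#'   `minmax_scale_apply`: the scaled matrix.
#' @export
minmax_scale_fit <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) == 0L) gf_data_error("cannot fit a scaler on an empty training set")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  structure(list(min = mins, max = maxs, constant = maxs == mins,
                 features = colnames(X)), class = "minmax_scaler")
}

#' @rdname minmax_scale_fit
#' @param scaler a fitted `minmax_scaler`.
#' @export
minmax_scale_apply <- function(scaler, features) {
  X <- as.matrix(features)
  if (!is.null(scaler$features)) {
    missing <- setdiff(scaler$features, colnames(X))
    if (length(missing)) gf_schema_error("missing feature columns: %s",
                                         paste(missing, collapse = ", "))
    X <- X[, scaler$features, drop = FALSE]
  }
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1
  out <- sweep(sweep(X, 2, scaler$min, "-"), 2, rng, "/")
  out[, scaler$constant] <- 0
  out
}

#' Stratified train/test split
#'
#' @param cohort cohort data frame with a `risk_label` column.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @param stratified preserve the label proportions (default TRUE).
#' @return list with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_train_test <- function(cohort, train_fraction = 0.7, seed = 1L, stratified = TRUE) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    gf_param_error("train_fraction must lie strictly between 0 and 1")
  }
  if (nrow(cohort) < 10L) gf_data_error("cohort too small to split (need >= 10 records)")
  set.seed(seed)
  n <- nrow(cohort)
  if (stratified) {
    train_idx <- integer(0)
    for (g in unique(cohort$risk_label)) {
      idx <- which(cohort$risk_label == g)
      take <- round(length(idx) * train_fraction)
      train_idx <- c(train_idx, sample(idx, take))
    }
  } else {
    train_idx <- sample.int(n, round(n * train_fraction))
  }
  list(train = cohort[sort(train_idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(n), train_idx)), , drop = FALSE])
}

label_to_binary <- function(labels) as.integer(labels == "high")

#' Cross-validated model selection on the training set
#'
#' Runs k-fold cross-validation (stratified fold assignment) over a grid of
#' candidate configurations and selects the one with the best mean validation
#' AUC; ties go to the simpler model (fewer trees, then shallower). The
#' scaler is refit inside every fold, so no information leaks from the
#' held-out fold.
#'
#' @param train training data frame (with `risk_label`).
#' @param config a [model_config()] supplying folds, seed, and defaults.
#' @param features predictor column names.
#' @param grid data frame of candidate overrides (columns among `n_trees`,
#'   `max_depth`, `learning_rate`, `gamma`, `lambda`); a single row by default.
#' @return list with `results` (per-candidate mean/sd AUC) and `config` (the
#'   selected [model_config()]).
#' @export
cross_validate <- function(train, config = model_config(),
                           features = speed_feature_set("preferred"),
                           grid = NULL) {
  k <- config$cv_folds
  if (nrow(train) < k) gf_param_error("more folds (%d) than records (%d)", k, nrow(train))
  if (is.null(grid)) grid <- data.frame(n_trees = config$n_trees)
  set.seed(config$seed)
  y <- label_to_binary(train$risk_label)
  folds <- integer(nrow(train))
  for (cls in unique(y)) {            # stratified fold assignment
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  results <- grid
  results$mean_auc <- NA_real_
  results$sd_auc <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][r]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- train[folds != f, , drop = FALSE]
      va <- train[folds == f, , drop = FALSE]
      scaler <- minmax_scale_fit(tr[, features, drop = FALSE])
      fit <- fit_gbt(minmax_scale_apply(scaler, tr[, features, drop = FALSE]),
                     label_to_binary(tr$risk_label),
                     n_trees = cfg$n_trees, learning_rate = cfg$learning_rate,
                     max_depth = cfg$max_depth, gamma = cfg$gamma,
                     lambda = cfg$lambda, min_child_weight = cfg$min_child_weight)
      scores <- predict(fit, minmax_scale_apply(scaler, va[, features, drop = FALSE]))
      roc_auc(scores, label_to_binary(va$risk_label))$auc
    }, numeric(1))
    results$mean_auc[r] <- mean(aucs)
    results$sd_auc[r] <- stats::sd(aucs)
  }
  # best mean AUC; ties -> fewer trees, then shallower
  ord <- order(-results$mean_auc,
               if ("n_trees" %in% names(grid)) grid$n_trees else rep(0, nrow(grid)),
               if ("max_depth" %in% names(grid)) grid$max_depth else rep(0, nrow(grid)))
  best <- ord[1]
  cfg <- config
  for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][best]
  list(results = results, config = cfg)
}

#' Train a fall-risk model on a training set
#'
#' Fits the min-max scaler on the training features, then the boosted-tree
#' classifier; the returned object carries both, plus gain-based feature
#' importance.
#'
#' @param train training data frame with `risk_label` and the feature columns.
#' @param config a [model_config()].
#' @param features predictor column names (default: preferred-speed set).
#' @return an object of class `fall_risk_model`.
#' @export
train_model <- function(train, config = model_config(),
                        features = speed_feature_set("preferred")) {
  missing <- setdiff(features, names(train))
  if (length(missing)) gf_schema_error("training set lacks feature columns: %s",
                                       paste(missing, collapse = ", "))
  y <- label_to_binary(train$risk_label)
  if (length(unique(y)) < 2L) gf_data_error("training set contains a single class")
  scaler <- minmax_scale_fit(train[, features, drop = FALSE])
  X <- minmax_scale_apply(scaler, train[, features, drop = FALSE])
  fit <- fit_gbt(X, y, n_trees = config$n_trees, learning_rate = config$learning_rate,
                 max_depth = config$max_depth, gamma = config$gamma,
                 lambda = config$lambda, min_child_weight = config$min_child_weight)
  importance <- fit$gain_by_feature
  names(importance) <- features
  structure(list(fit = fit, scaler = scaler, features = features,
                 config = config, importance = importance),
            class = "fall_risk_model")
}

#' Predict fall-risk probability and label
#'
#' @param model a [train_model()] result.
#' @param newdata data frame containing the model's feature columns (extra
#'   columns and any column order are fine).
#' @param threshold probability cut for `"high"`; defaults to the model
#'   config's threshold. A score exactly at the threshold is labelled high.
#' @return data frame with `score` and `label` columns.
#' @export
predict_risk <- function(model, newdata, threshold = NULL) {
  if (!inherits(model, "fall_risk_model")) gf_param_error("model must be a fall_risk_model")
  if (is.null(threshold)) threshold <- model$config$threshold
  missing <- setdiff(model$features, names(newdata))
  if (length(missing)) gf_schema_error("missing feature columns: %s",
                                       paste(missing, collapse = ", "))
  X <- minmax_scale_apply(model$scaler, newdata[, model$features, drop = FALSE])
  scores <- predict(model$fit, X)
  data.frame(score = scores, label = ifelse(scores >= threshold, "high", "low"))
}

#' Gain-based feature importance ranking
#'
#' @param model a [train_model()] result.
#' @param top_k number of entries to return.
#' @param normalize scale the scores to sum to 1.
#' @return data frame with `feature` and `score`, descending; ties broken
#'   alphabetically.
#' @export
feature_importance_ranking <- function(model, top_k = 10L, normalize = FALSE) {
  imp <- model$importance
  if (normalize && sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  out <- data.frame(feature = names(imp)[ord], score = unname(imp[ord]))
  utils::head(out, top_k)
}

#' Save / load a trained model as a portable JSON bundle
#'
#' Serializes the tree list, scaler, feature set and configuration; a loaded
#' model reproduces the original predictions exactly.
#'
#' @param model a `fall_risk_model`.
#' @param path JSON file path.
#' @return `save_model_json` returns `path` invisibly; `load_model_json`
#'   returns the model.
#' @export
save_model_json <- function(model, path) {
  bundle <- list(
    base = model$fit$base, learning_rate = model$fit$learning_rate,
    params = model$fit$params,
    trees = lapply(model$fit$trees, function(t) as.list(as.data.frame(t))),
    scaler = list(min = as.list(model$scaler$min), max = as.list(model$scaler$max),
                  constant = as.list(model$scaler$constant)),
    features = model$features, config = unclass(model$config),
    importance = as.list(model$importance)
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  trees <- lapply(b$trees, function(t) {
    cbind(feature = as.numeric(t$feature), threshold = as.numeric(t$threshold),
          left = as.numeric(t$left), right = as.numeric(t$right),
          weight = as.numeric(t$weight), gain = as.numeric(t$gain),
          cover = as.numeric(t$cover))
  })
  fit <- structure(list(trees = trees, base = b$base, learning_rate = b$learning_rate,
                        feature_names = b$features,
                        gain_by_feature = unname(unlist(b$importance)),
                        params = b$params), class = "gbt")
  scaler <- structure(list(min = unlist(b$scaler$min), max = unlist(b$scaler$max),
                           constant = unlist(b$scaler$constant), features = b$features),
                      class = "minmax_scaler")
  cfg <- b$config
  class(cfg) <- "model_config"
  structure(list(fit = fit, scaler = scaler, features = b$features, config = cfg,
                 importance = unlist(b$importance)),
            class = "fall_risk_model")
}
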