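test_that("min-max scaler maps train to [0,1], handles constants and extrapolates", {
  sc <- minmax_scale_fit(data.frame(a = c(1, 2, 3)))
  expect_equal(as.numeric(minmax_scale_apply(sc, data.frame(a = c(1, 2, 3)))),
               c(0, 0.5, 1))
  sc2 <- minmax_scale_fit(data.frame(a = c(1, 3), b = c(5, 5)))
  expect_true(sc2$constant[["b"]])
  out <- minmax_scale_apply(sc2, data.frame(a = 4, b = 7))
  expect_equal(as.numeric(out), c(1.5, 0))          # no clipping; constants -> 0
  expect_error(minmax_scale_fit(data.frame(a = numeric(0))), class = "gaitfall_data_error")
  expect_error(minmax_scale_apply(sc, data.frame(zz = 1)), class = "gaitfall_schema_error")
})

test_that("stratified 70/30 split preserves counts and proportions", {
  co <- simulate_cohort(default_cohort_spec(seed = 2))
  parts <- split_train_test(co, 0.7, seed = 1)
  expect_equal(nrow(parts$train), 522, tolerance = 1)
  expect_equal(nrow(parts$test), 224, tolerance = 1)
  expect_equal(nrow(parts$train) + nrow(parts$test), 746)
  expect_length(intersect(parts$train$participant_id, parts$test$participant_id), 0)
  expect_equal(sum(parts$train$risk_label == "high"), round(290 * 0.7), tolerance = 1)
  parts2 <- split_train_test(co, 0.7, seed = 1)
  expect_identical(parts$train$participant_id, parts2$train$participant_id)
  expect_error(split_train_test(co, 1.0), class = "gaitfall_parameter_error")
  expect_error(split_train_test(co[1:5, ], 0.7), class = "gaitfall_data_error")
})

test_that("a single boosting stump matches a brute-force objective oracle", {
  set.seed(3)
  X <- matrix(round(runif(24), 3), 12, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0)
  lambda <- 1.5
  p0 <- mean(y)
  g <- p0 - y; h <- rep(p0 * (1 - p0), 12)
  # oracle: exhaustive split enumeration with the regularized gain formula
  best <- list(gain = 0)
  for (j in 1:2) {
    for (thr in sort(unique(X[, j]))[-1]) {
      L <- X[, j] < thr
      GL <- sum(g[L]); HL <- sum(h[L]); GR <- sum(g[!L]); HR <- sum(h[!L])
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
                     (GL + GR)^2 / (HL + HR + lambda))
      if (gain > best$gain) best <- list(gain = gain, j = j, thr = thr, L = L)
    }
  }
  w_l <- -sum(g[best$L]) / (sum(h[best$L]) + lambda)
  w_r <- -sum(g[!best$L]) / (sum(h[!best$L]) + lambda)
  expected <- plogis(log(p0 / (1 - p0)) + ifelse(best$L, w_l, w_r))

  fit <- fit_gbt(X, y, n_trees = 1L, learning_rate = 1, max_depth = 1L,
                 gamma = 0, lambda = lambda, min_child_weight = 0)
  expect_equal(predict(fit, X), expected, tolerance = 1e-12)
})

test_that("training is deterministic and leak-free", {
  co <- small_cohort(n = 150, seed = 5)
  parts <- split_train_test(co, 0.7, seed = 5)
  cfg <- model_config(n_trees = 30L, seed = 5)
  feats <- speed_feature_set("preferred")
  m1 <- train_model(parts$train, cfg, feats)
  m2 <- train_model(parts$train, cfg, feats)
  expect_identical(predict_risk(m1, parts$test)$score, predict_risk(m2, parts$test)$score)
  # shuffling the held-out labels cannot change a model that never saw them
  shuffled <- parts$test
  shuffled$risk_label <- sample(shuffled$risk_label)
  expect_identical(predict_risk(m1, parts$test)$score, predict_risk(m1, shuffled)$score)
})

test_that("the single informative feature dominates the importance ranking", {
  d <- flat_dist_table(list(preferred_stride_length = c(0.9, 1.4)))
  d$sd[d$variable == "preferred_gait_asymmetry"] <- 0   # zero-variance feature
  co <- small_cohort(n = 300, seed = 6, dist = d)
  m <- train_model(co, model_config(n_trees = 50L, seed = 6),
                   speed_feature_set("preferred"))
  ranking <- feature_importance_ranking(m, top_k = 14L, normalize = TRUE)
  expect_identical(ranking$feature[1], "preferred_stride_length")
  expect_gt(ranking$score[1], 0.5)
  expect_equal(sum(ranking$score), 1)
  expect_equal(m$importance[["preferred_gait_asymmetry"]], 0)
  expect_lte(nrow(feature_importance_ranking(m, top_k = 10L)), 10)
})

test_that("predict_risk enforces the schema and the threshold convention", {
  co <- small_cohort(n = 120, seed = 7)
  m <- train_model(co, model_config(n_trees = 20L, seed = 7),
                   speed_feature_set("preferred"))
  newdata <- co[1:10, ]
  p1 <- predict_risk(m, newdata)
  # column order is irrelevant (schema-keyed)
  p2 <- predict_risk(m, newdata[, rev(names(newdata))])
  expect_identical(p1$score, p2$score)
  # a score exactly at the threshold is labelled high
  p3 <- predict_risk(m, newdata, threshold = p1$score[1])
  expect_identical(p3$label[1], "high")
  broken <- newdata[, setdiff(names(newdata), "age")]
  expect_error(predict_risk(m, broken), "age", class = "gaitfall_schema_error")
})

test_that("mean training prediction approximates the training prevalence", {
  co <- small_cohort(n = 250, seed = 8)
  m <- train_model(co, model_config(n_trees = 100L, seed = 8),
                   speed_feature_set("preferred"))
  scores <- predict_risk(m, co)$score
  expect_equal(mean(scores), mean(co$risk_label == "high"), tolerance = 0.05)
})

test_that("single-class training sets are rejected", {
  co <- small_cohort(n = 100, seed = 9)
  co$risk_label <- "low"
  expect_error(train_model(co, model_config(), speed_feature_set("preferred")),
               class = "gaitfall_data_error")
})

test_that("cross-validation is perfect on separable data and null on permuted labels", {
  sep <- small_cohort(n = 100, seed = 10,
                      dist = flat_dist_table(list(preferred_walking_speed = c(0.5, 2.0)),
                                             sd = 0.05))
  cv <- cross_validate(sep, model_config(n_trees = 30L, cv_folds = 5L, seed = 10),
                       speed_feature_set("preferred"))
  expect_equal(cv$results$mean_auc, 1.0)

  co <- simulate_cohort(default_cohort_spec(seed = 11))
  set.seed(11)
  co$risk_label <- sample(co$risk_label)
  # smaller trees than the analysis default purely to keep the null check fast
  cv0 <- cross_validate(co, model_config(n_trees = 50L, max_depth = 2L,
                                         cv_folds = 10L, seed = 11),
                        speed_feature_set("preferred"))
  expect_gt(cv0$results$mean_auc, 0.4)
  expect_lt(cv0$results$mean_auc, 0.6)

  expect_error(cross_validate(small_cohort(n = 9, seed = 1),
                              model_config(cv_folds = 10L)),
               class = "gaitfall_parameter_error")
})

test_that("cross-validation selects over a grid with simplicity tie-breaks", {
  co <- small_cohort(n = 120, seed = 12)
  grid <- data.frame(n_trees = c(10L, 25L), max_depth = c(2L, 3L))
  cv <- cross_validate(co, model_config(cv_folds = 4L, seed = 12),
                       speed_feature_set("preferred"), grid = grid)
  expect_identical(nrow(cv$results), 2L)
  expect_true(cv$config$n_trees %in% grid$n_trees)
  expect_false(any(is.na(cv$results$mean_auc)))
})

test_that("a wider group separation strictly increases mean test AUC", {
  gaps <- c(0.05, 0.15, 0.35)
  mean_auc <- vapply(gaps, function(gap) {
    aucs <- vapply(1:10, function(seed) {
      d <- flat_dist_table(list(preferred_walking_speed = c(1.15 - gap / 2, 1.15 + gap / 2)),
                           sd = 0.2)
      co <- small_cohort(n = 300, seed = seed, dist = d)
      parts <- split_train_test(co, 0.7, seed = seed)
      m <- train_model(parts$train, model_config(n_trees = 60L, seed = seed),
                       speed_feature_set("preferred"))
      roc_auc(predict_risk(m, parts$test)$score, parts$test$risk_label)$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) > 0))
})
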