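test_that("confusion counts cross-tabulate correctly", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  perfect <- confusion(c("high", "low"), c("high", "low"))
  expect_equal(perfect$fn + perfect$fp, 0)
  all_low <- confusion(c(1, 1, 0), c(0, 0, 0))
  expect_equal(all_low$tp + all_low$fp, 0)
  expect_error(confusion(c(1, 0), c(1)), class = "gaitfall_data_error")
})

test_that("the rate panel follows the defining formulas", {
  r <- rates(list(tp = 43, fn = 57, fp = 16, tn = 84))
  expect_equal(r$sensitivity, 0.43)
  expect_equal(r$specificity, 0.84)
  expect_equal(r$accuracy, 127 / 200)
  expect_equal(r$ppv, 43 / 59)
  expect_equal(r$npv, 84 / 141)
  expect_equal(r$plr, 0.43 / 0.16)
  expect_equal(r$nlr, 0.57 / 0.84)

  r2 <- rates(list(tp = 50, fn = 50, fp = 20, tn = 80))
  expect_equal(r2$plr, 2.5)
  expect_equal(r2$nlr, 0.625)

  perfect <- rates(list(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$nlr, 0)
  degenerate <- rates(list(tp = 0, fn = 0, fp = 2, tn = 3))
  expect_true(is.nan(degenerate$sensitivity))
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(4)
  for (i in 1:20) {
    cc <- list(tp = sample(0:30, 1), fn = sample(1:30, 1),
               fp = sample(1:30, 1), tn = sample(1:30, 1))
    cc$tp <- cc$tp + 1
    r <- rates(cc)
    prev <- (cc$tp + cc$fn) / (cc$tp + cc$fn + cc$fp + cc$tn)
    expect_equal(r$accuracy, prev * r$sensitivity + (1 - prev) * r$specificity)
  }
})

test_that("roc_auc matches known rankings and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "gaitfall_data_error")
  ra <- roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
})

test_that("fast AUC equals brute-force pair counting on random instances", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # forces ties
    expect_identical(roc_auc(scores, y)$auc, auc_brute_force(scores, y))
  }
})

test_that("Wilson intervals match the score-test quadratic roots", {
  # independent oracle: endpoints solve (p-hat - p)^2 = z^2 p(1-p)/n
  wilson_roots <- function(x, n, level = 0.95) {
    z2 <- stats::qnorm(1 - (1 - level) / 2)^2
    ph <- x / n
    sort(Re(polyroot(c(ph^2, -2 * ph - z2 / n, 1 + z2 / n))))
  }
  expect_equal(wilson_ci(43, 100), wilson_roots(43, 100), tolerance = 1e-10)
  expect_equal(wilson_ci(43, 100), c(0.33733, 0.52785), tolerance = 1e-4)
  ci50 <- wilson_ci(50, 100)
  expect_equal(ci50[1] + ci50[2], 1, tolerance = 1e-12)      # symmetric about 0.5
  expect_equal(wilson_ci(100, 100)[2], 1)
})

test_that("likelihood-ratio intervals follow the log method", {
  cc <- list(tp = 43, fn = 57, fp = 16, tn = 84)
  ci <- confidence_intervals(cc, scores = c(1, 0), labels = c(1, 0))
  z <- stats::qnorm(0.975)
  se_plr <- sqrt(1 / 43 - 1 / 100 + 1 / 16 - 1 / 100)
  expect_equal(ci$plr, exp(log(0.43 / 0.16) + c(-1, 1) * z * se_plr), tolerance = 1e-12)
  se_nlr <- sqrt(1 / 57 - 1 / 100 + 1 / 84 - 1 / 100)
  expect_equal(ci$nlr, exp(log(0.57 / 0.84) + c(-1, 1) * z * se_nlr), tolerance = 1e-12)
  expect_true(ci$plr[1] <= 0.43 / 0.16 && 0.43 / 0.16 <= ci$plr[2])
})

test_that("DeLong AUC interval behaves sensibly and clips at 1", {
  set.seed(5)
  y <- rep(c(1, 0), each = 50)
  x <- c(rnorm(50, 1), rnorm(50, 0))
  d <- gaitfall:::delong_ci(x, y)
  expect_true(d$ci[1] < d$auc && d$auc < d$ci[2])
  # separable scores: AUC 1, upper bound clipped to 1
  sep <- gaitfall:::delong_ci(c(2, 3, 4, -1, 0, 1) + c(10, 10, 10, 0, 0, 0),
                              c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$ci[2], 1)
  # variance shrinks with sample size
  y2 <- rep(c(1, 0), each = 500)
  x2 <- c(rnorm(500, 1), rnorm(500, 0))
  expect_lt(gaitfall:::delong_ci(x2, y2)$var, d$var)
})

test_that("group descriptives flag real differences and not null ones", {
  g <- data.frame(risk_label = rep(c("high", "low"), each = 3),
                  age = c(1, 2, 3, 1, 2, 3))
  d <- group_descriptives(g, "age")
  expect_equal(d$mean_high - d$mean_low, 0)
  expect_equal(d$t_p, 1)

  # power: N(0,1) vs N(1,1) at n=500 per group is essentially always significant
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    co <- data.frame(risk_label = rep(c("high", "low"), each = 500),
                     v = c(rnorm(500, 0), rnorm(500, 1)))
    group_descriptives(co, "v")$t_p < 0.001
  }, logical(1))
  expect_gte(sum(hits), 99)

  tiny <- data.frame(risk_label = c("high", "high", "low", "low", "low"),
                     v = c(1, 2, 1, 2, 3))
  expect_true(is.na(group_descriptives(tiny, "v")$shapiro_p_high))
  expect_error(group_descriptives(data.frame(risk_label = "high", v = 1), "v"),
               class = "gaitfall_data_error")
})

test_that("full reports satisfy internal identities and serialize stably", {
  co <- small_cohort(n = 150, seed = 13)
  parts <- split_train_test(co, 0.7, seed = 13)
  m <- train_model(parts$train, model_config(n_trees = 30L, seed = 13),
                   speed_feature_set("preferred"))
  r <- full_report(m, parts$test, "preferred")
  expect_equal(r$metrics$plr,
               r$metrics$sensitivity / (1 - r$metrics$specificity), tolerance = 1e-12)
  expect_equal(r$confusion$tp + r$confusion$fn + r$confusion$fp + r$confusion$tn,
               r$n_test)
  expect_true(all(r$ci$auc[1] <= r$metrics$auc, r$metrics$auc <= r$ci$auc[2]))

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, p1)
  write_report_json(full_report(m, parts$test, "preferred"), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  back <- read_report_json(p1)
  expect_equal(back$metrics$auc, r$metrics$auc, tolerance = 1e-12)
  expect_equal(unlist(back$ci), unlist(r$ci), tolerance = 1e-12)
})
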