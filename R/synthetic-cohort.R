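GAIT_SPEEDS <- c("slower", "preferred", "faster")
GAIT_FEATURES <- c("walking_speed", "stride_length", "cadence", "stance_phase",
                   "stride_time", "cv_stride_length", "cv_stance_phase",
                   "cv_stride_time", "gait_asymmetry")
DEMO_FEATURES <- c("age", "height_cm", "bmi", "pa_met_min_wk", "education_level", "mmse")

#' Gait variable column names, speed-major
#'
#' The 27 `<speed>_<feature>` column names in the order used throughout the
#' package (all nine slower-speed variables, then preferred, then faster);
#' a user-supplied `feature_correlation` matrix is indexed in this order.
#'
#' @return character vector of length 27.
#' @export
gait_variable_names <- function() {
  unlist(lapply(GAIT_SPEEDS, function(s) paste(s, GAIT_FEATURES, sep = "_")),
         use.names = FALSE)
}

#' Cohort simulation specification
#'
#' Group-specific marginal distributions (mean and SD per high/low fall-risk
#' group) for the 27 per-speed gait variables and six demographic/cognitive
#' variables, plus the cohort size, high-risk prevalence, and an optional
#' correlation matrix over the gait variables. [default_cohort_spec()] fills
#' in the published older-adult cohort values.
#'
#' @param n_participants cohort size.
#' @param p_high_risk probability (or exact fraction, see
#'   `exact_stratification`) of the high-risk label.
#' @param dist data frame with columns `variable`, `group` (`high`/`low`),
#'   `mean`, `sd` covering every gait and demographic variable.
#' @param feature_correlation `"independent"` (default) or a positive
#'   semi-definite correlation matrix over the 27 gait variables (Gaussian
#'   copula on the marginals).
#' @param exact_stratification draw exactly `round(n * p_high_risk)` high-risk
#'   records instead of independent Bernoulli labels.
#' @param p_female probability of female sex (same in both groups; the source
#'   cohort's sex split is unpublished).
#' @param rule [risk_rule()] used to synthesize label-consistent
#'   questionnaires.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, p_high_risk, dist,
                        feature_correlation = "independent",
                        exact_stratification = FALSE,
                        p_female = 0.5, rule = risk_rule(), seed = 1L) {
  if (!is_count(n_participants, min = 1L)) gf_param_error("n_participants must be a positive integer")
  if (!is_number(p_high_risk) || p_high_risk < 0 || p_high_risk > 1) {
    gf_param_error("p_high_risk must lie in [0, 1]")
  }
  need <- c("variable", "group", "mean", "sd")
  if (!is.data.frame(dist) || !all(need %in% names(dist))) {
    gf_param_error("dist must be a data frame with columns %s", paste(need, collapse = ", "))
  }
  gait_vars <- gait_variable_names()
  all_vars <- c(DEMO_FEATURES, gait_vars)
  for (g in c("high", "low")) {
    have <- dist$variable[dist$group == g]
    missing <- setdiff(all_vars, have)
    if (length(missing)) {
      gf_param_error("dist is missing %s rows for: %s", g, paste(missing, collapse = ", "))
    }
  }
  if (any(dist$sd < 0)) gf_param_error("all SDs must be >= 0")
  if (!identical(feature_correlation, "independent")) {
    R <- feature_correlation
    if (!is.matrix(R) || nrow(R) != length(gait_vars) || ncol(R) != length(gait_vars)) {
      gf_param_error("feature_correlation must be 'independent' or a %dx%d matrix",
                     length(gait_vars), length(gait_vars))
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) gf_param_error("feature_correlation must be positive semi-definite")
  }
  if (!inherits(rule, "risk_rule")) gf_param_error("rule must be a risk_rule")
  structure(list(
    n_participants = as.integer(n_participants), p_high_risk = p_high_risk,
    dist = dist, feature_correlation = feature_correlation,
    exact_stratification = exact_stratification, p_female = p_female,
    rule = rule, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Published group means and SDs for the default cohort
#'
#' Demographics and cognition, then the nine gait variables at each of the
#' three walking speeds; one row per (variable, group) with the high-risk
#' group first.
#'
#' @return data frame with columns `variable`, `group`, `mean`, `sd`.
#' @export
default_dist_table <- function() {
  row <- function(variable, mh, sh, ml, sl) {
    data.frame(variable = variable, group = c("high", "low"),
               mean = c(mh, ml), sd = c(sh, sl))
  }
  demo <- rbind(
    row("age", 74.2, 5.4, 72.2, 4.9),
    row("height_cm", 158.0, 8.2, 156.9, 8.1),
    row("bmi", 25.1, 3.1, 24.5, 2.7),
    row("pa_met_min_wk", 1389.7, 1409.7, 2182.6, 1932.4),
    row("education_level", 1.7, 1.1, 2.3, 1.1),
    row("mmse", 25.7, 3.3, 26.9, 2.6)
  )
  gait <- rbind(
    row("slower_walking_speed", 0.8, 0.1, 0.9, 0.1),
    row("slower_stride_length", 1.1, 0.1, 1.2, 0.1),
    row("slower_cadence", 97.9, 11.1, 97.7, 10.7),
    row("slower_stance_phase", 59.5, 1.7, 59.0, 1.6),
    row("slower_stride_time", 1.2, 0.1, 1.2, 0.1),
    row("slower_cv_stride_length", 3.0, 1.4, 2.5, 1.2),
    row("slower_cv_stance_phase", 5.0, 2.5, 4.2, 2.0),
    row("slower_cv_stride_time", 3.0, 1.4, 2.5, 1.1),
    row("slower_gait_asymmetry", 2.8, 2.6, 2.5, 2.3),
    row("preferred_walking_speed", 1.1, 0.2, 1.2, 0.2),
    row("preferred_stride_length", 1.1, 0.2, 1.3, 0.1),
    row("preferred_cadence", 114.8, 10.3, 116.7, 10.1),
    row("preferred_stance_phase", 58.0, 1.8, 57.2, 1.6),
    row("preferred_stride_time", 1.0, 0.1, 1.0, 0.1),
    row("preferred_cv_stride_length", 2.2, 1.3, 1.9, 0.9),
    row("preferred_cv_stance_phase", 3.3, 2.0, 2.8, 1.4),
    row("preferred_cv_stride_time", 2.2, 1.3, 1.9, 0.9),
    row("preferred_gait_asymmetry", 2.1, 2.1, 2.0, 2.0),
    row("faster_walking_speed", 1.4, 0.2, 1.5, 0.2),
    row("faster_stride_length", 1.3, 0.2, 1.4, 0.2),
    row("faster_cadence", 127.8, 12.1, 131.8, 11.1),
    row("faster_stance_phase", 56.3, 1.9, 55.3, 1.7),
    row("faster_stride_time", 0.9, 0.1, 0.9, 0.1),
    row("faster_cv_stride_length", 2.0, 1.3, 1.7, 0.8),
    row("faster_cv_stance_phase", 2.6, 1.4, 2.2, 1.1),
    row("faster_cv_stride_time", 2.0, 1.3, 1.7, 0.8),
    row("faster_gait_asymmetry", 2.3, 2.2, 1.9, 1.8)
  )
  rbind(demo, gait)
}

#' Default cohort specification (published cohort marginals)
#'
#' 746 participants with a 290/456 high/low split; every group mean and SD
#' equals the published older-adult cohort value (demographics, cognition and
#' the 9 gait variables at each of three walking speeds). Gait variables are
#' drawn independently by default, which is documented as making the
#' classification task easier than the (correlated) real data.
#'
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(...) {
  args <- list(n_participants = 746L, p_high_risk = 290 / 746,
               dist = default_dist_table(), exact_stratification = TRUE)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

#' Look up a mean or SD in a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @param variable variable name, e.g. `"slower_stance_phase"`.
#' @param group `"high"` or `"low"`.
#' @param what `"mean"` or `"sd"`.
#' @return the stored value.
#' @export
spec_param <- function(spec, variable, group, what = "mean") {
  i <- which(spec$dist$variable == variable & spec$dist$group == group)
  if (length(i) != 1L) gf_param_error("no unique dist row for %s/%s", variable, group)
  spec$dist[[what]][i]
}

#' Simulate a labelled cohort feature table
#'
#' Each participant receives a risk label (exact counts or Bernoulli), a
#' questionnaire that reproduces the label under the spec's rule, and
#' demographic plus per-speed gait features drawn from the label's group
#' distributions. All numeric features are plain normal draws so that the
#' group-wise sample moments converge to the configured values.
#'
#' @param spec a [cohort_spec()].
#' @return data frame, one row per participant, with id, label, questionnaire,
#'   demographic and `<speed>_<feature>` columns.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) gf_param_error("spec must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_participants
  if (isTRUE(spec$exact_stratification)) {
    n_high <- round(n * spec$p_high_risk)
    labels <- sample(c(rep("high", n_high), rep("low", n - n_high)))
  } else {
    labels <- ifelse(stats::runif(n) < spec$p_high_risk, "high", "low")
  }
  q <- lapply(labels, sample_questionnaire, rule = spec$rule)
  gait_vars <- gait_variable_names()
  all_vars <- c(DEMO_FEATURES, gait_vars)

  draw_group <- function(group, m) {
    mu <- vapply(all_vars, spec_param, numeric(1), spec = spec, group = group, what = "mean")
    sg <- vapply(all_vars, spec_param, numeric(1), spec = spec, group = group, what = "sd")
    z <- matrix(stats::rnorm(m * length(all_vars)), nrow = m)
    if (!identical(spec$feature_correlation, "independent")) {
      gi <- match(gait_vars, all_vars)
      L <- chol(spec$feature_correlation, pivot = FALSE)
      z[, gi] <- z[, gi, drop = FALSE] %*% L
    }
    sweep(sweep(z, 2, sg, "*"), 2, mu, "+")
  }
  X <- matrix(NA_real_, nrow = n, ncol = length(all_vars),
              dimnames = list(NULL, all_vars))
  for (g in c("high", "low")) {
    idx <- which(labels == g)
    if (length(idx)) X[idx, ] <- draw_group(g, length(idx))
  }
  out <- data.frame(
    participant_id = seq_len(n),
    risk_label = labels,
    sex = as.integer(stats::runif(n) < spec$p_female),   # 1 = female
    fell_6mo = vapply(q, function(x) x$fell_6mo, logical(1)),
    n_falls_6mo = vapply(q, function(x) x$n_falls_6mo, integer(1)),
    fear_of_falling = vapply(q, function(x) x$fear_of_falling, logical(1))
  )
  cbind(out, as.data.frame(X))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data frame from [simulate_cohort()] (or matching layout).
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"risk_label" %in% names(d)) gf_schema_error("cohort CSV must have a risk_label column")
  d
}

#' Re-derive risk labels for a cohort from its questionnaire columns
#'
#' @param cohort cohort data frame with `fell_6mo`, `n_falls_6mo`,
#'   `fear_of_falling` columns.
#' @param rule a [risk_rule()].
#' @return character vector of `"high"`/`"low"` labels.
#' @export
label_cohort <- function(cohort, rule = risk_rule()) {
  vapply(seq_len(nrow(cohort)), function(i) {
    classify_fall_risk(fall_questionnaire(
      as.logical(cohort$fell_6mo[i]), as.integer(cohort$n_falls_6mo[i]),
      as.logical(cohort$fear_of_falling[i])), rule)
  }, character(1))
}
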