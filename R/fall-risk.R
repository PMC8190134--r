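#' Fall-history questionnaire
#'
#' Three items screen fall risk in older adults: whether the person fell in
#' the last 6 months, how many times, and whether they are afraid of falling.
#'
#' @param fell_6mo logical; must equal `n_falls_6mo > 0`.
#' @param n_falls_6mo non-negative integer count of falls in the last 6 months.
#' @param fear_of_falling logical.
#' @return an object of class `fall_questionnaire`.
#' @export
fall_questionnaire <- function(fell_6mo, n_falls_6mo, fear_of_falling) {
  if (!is_count(n_falls_6mo)) gf_param_error("n_falls_6mo must be a non-negative integer")
  if (!is_flag(fell_6mo) || !is_flag(fear_of_falling)) {
    gf_param_error("fell_6mo and fear_of_falling must be TRUE or FALSE")
  }
  if (fell_6mo != (n_falls_6mo > 0)) {
    gf_param_error("fell_6mo must be consistent with n_falls_6mo (%d)", n_falls_6mo)
  }
  structure(list(fell_6mo = fell_6mo, n_falls_6mo = as.integer(n_falls_6mo),
                 fear_of_falling = fear_of_falling), class = "fall_questionnaire")
}

RISK_BANDS <- c("0", "1", "2+")

#' Fall-risk decision rule
#'
#' A decision table over falls bands (0, 1, >= 2 falls) crossed with fear of
#' falling, mapping each of the six cells to `"high"` or `"low"`. The default
#' rule labels two or more falls high risk regardless of fear, one fall high
#' risk only with fear of falling, and everything else low risk. Any
#' user-supplied rule should be monotone (more falls or added fear never
#' lowers risk); see [validate_rule()].
#'
#' @param table named character vector of `"high"`/`"low"` with names
#'   `"<band>_<fear>"` where band is `0`, `1` or `2+` and fear `nofear`/`fear`.
#' @return an object of class `risk_rule`.
#' @export
risk_rule <- function(table = NULL) {
  cells <- as.vector(outer(RISK_BANDS, c("nofear", "fear"), paste, sep = "_"))
  if (is.null(table)) {
    table <- c("0_nofear" = "low", "0_fear" = "low",
               "1_nofear" = "low", "1_fear" = "high",
               "2+_nofear" = "high", "2+_fear" = "high")
  }
  if (!setequal(names(table), cells)) {
    gf_param_error("rule table must name exactly the cells: %s", paste(cells, collapse = ", "))
  }
  if (!all(table %in% c("high", "low"))) gf_param_error("rule cells must be 'high' or 'low'")
  structure(list(table = table[cells]), class = "risk_rule")
}

falls_band <- function(n_falls) ifelse(n_falls >= 2L, "2+", as.character(n_falls))

#' Classify fall risk from the questionnaire
#'
#' @param q a [fall_questionnaire()].
#' @param rule a [risk_rule()]; defaults to the package rule.
#' @return `"high"` or `"low"`.
#' @examples
#' classify_fall_risk(fall_questionnaire(TRUE, 3L, TRUE))   # "high"
#' classify_fall_risk(fall_questionnaire(FALSE, 0L, FALSE)) # "low"
#' @export
classify_fall_risk <- function(q, rule = risk_rule()) {
  if (!inherits(q, "fall_questionnaire")) gf_param_error("q must be a fall_questionnaire")
  if (!inherits(rule, "risk_rule")) gf_param_error("rule must be a risk_rule")
  cell <- paste0(falls_band(q$n_falls_6mo), "_", if (q$fear_of_falling) "fear" else "nofear")
  unname(rule$table[[cell]])
}

#' Check a fall-risk rule for monotonicity
#'
#' Exhaustively verifies over the six decision cells that increasing the falls
#' band or adding fear of falling never changes a `"high"` label to `"low"`.
#'
#' @param rule a [risk_rule()].
#' @return list with `ok` (logical) and `violations` (character vector of
#'   offending cell pairs, empty when `ok`).
#' @export
validate_rule <- function(rule) {
  if (!inherits(rule, "risk_rule")) gf_param_error("rule must be a risk_rule")
  lvl <- function(x) if (x == "high") 1L else 0L
  viol <- character(0)
  for (fear in c("nofear", "fear")) {
    for (i in 1:2) {
      a <- paste0(RISK_BANDS[i], "_", fear); b <- paste0(RISK_BANDS[i + 1L], "_", fear)
      if (lvl(rule$table[[a]]) > lvl(rule$table[[b]])) viol <- c(viol, paste(a, "->", b))
    }
  }
  for (band in RISK_BANDS) {
    a <- paste0(band, "_nofear"); b <- paste0(band, "_fear")
    if (lvl(rule$table[[a]]) > lvl(rule$table[[b]])) viol <- c(viol, paste(a, "->", b))
  }
  list(ok = length(viol) == 0L, violations = viol)
}

#' Read a fall-risk rule from a JSON file
#'
#' The JSON object maps the six decision cells to `"high"`/`"low"`, e.g.
#' `{"0_nofear": "low", ...}`.
#'
#' @param path JSON file.
#' @return a [risk_rule()].
#' @export
read_rule_json <- function(path) {
  tab <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  risk_rule(tab)
}

# Sample a questionnaire consistent with a given label under a rule: pick a
# cell uniformly among the cells mapping to the label; falls counts in the
# "2+" band are 2 plus a small Poisson excess.
sample_questionnaire <- function(label, rule = risk_rule()) {
  cells <- names(rule$table)[rule$table == label]
  if (length(cells) == 0L) {
    gf_data_error("rule has no cell mapping to label '%s'; cannot synthesize questionnaire", label)
  }
  cell <- cells[sample.int(length(cells), 1L)]
  parts <- strsplit(cell, "_", fixed = TRUE)[[1]]
  n_falls <- switch(parts[1], "0" = 0L, "1" = 1L, "2+" = 2L + stats::rpois(1L, 0.5))
  fall_questionnaire(fell_6mo = n_falls > 0L, n_falls_6mo = n_falls,
                     fear_of_falling = parts[2] == "fear")
}
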