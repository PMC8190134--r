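# Internal condition helpers. All user-facing errors carry a subclass so tests
# and callers can distinguish bad parameters from bad data from failed detection.

gf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gaitfall_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

gf_param_error <- function(msg, ...) gf_stop("gaitfall_parameter_error", msg, ...)
gf_data_error <- function(msg, ...) gf_stop("gaitfall_data_error", msg, ...)
gf_detection_error <- function(msg, ...) gf_stop("gaitfall_detection_error", msg, ...)
gf_schema_error <- function(msg, ...) gf_stop("gaitfall_schema_error", msg, ...)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' Sample coefficient of variation, in percent
#'
#' CV = standard deviation / mean x 100, the standard stride-to-stride
#' variability measure for gait series. The sample (n-1) standard deviation is
#' the default; set `population = TRUE` for the n-denominator variant.
#'
#' @param values numeric vector, length >= 2.
#' @param population use the population (n) standard deviation instead of the
#'   sample (n-1) one.
#' @return CV in percent (non-negative for positive-mean series).
#' @examples
#' coefficient_of_variation(c(1.0, 1.1, 1.2))  # 9.09
#' @export
coefficient_of_variation <- function(values, population = FALSE) {
  if (!is.numeric(values) || length(values) < 2L) {
    gf_data_error("coefficient_of_variation() needs at least 2 numeric values")
  }
  m <- mean(values)
  if (m == 0) gf_stop("gaitfall_undefined_value_error", "CV undefined: mean is zero")
  s <- stats::sd(values)
  if (population) s <- s * sqrt((length(values) - 1) / length(values))
  s / m * 100
}
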