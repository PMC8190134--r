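#' Walking speed
#'
#' @param distance walked distance, meters.
#' @param duration walk duration, seconds (> 0).
#' @return speed in m/s.
#' @export
walking_speed <- function(distance, duration) {
  if (!is_number(duration) || duration <= 0) gf_param_error("duration must be > 0")
  if (!is_number(distance) || distance < 0) gf_param_error("distance must be >= 0")
  distance / duration
}

#' Cadence
#'
#' Steps per minute: step count x 60 / walking duration.
#'
#' @param step_count number of steps (heel strikes) in the window.
#' @param duration seconds (> 0).
#' @return cadence in steps/min.
#' @export
cadence <- function(step_count, duration) {
  if (!is_number(duration) || duration <= 0) gf_param_error("duration must be > 0")
  if (!is_count(step_count)) gf_param_error("step_count must be a non-negative integer")
  step_count * 60 / duration
}

#' Per-stride times from heel-strike indices
#'
#' Consecutive heel-strike sample differences divided by the sampling rate.
#'
#' @param hs strictly increasing heel-strike sample indices (>= 2).
#' @param sampling_rate Hz.
#' @return list with `per_stride` (seconds) and `mean`.
#' @examples
#' stride_times(c(0, 110, 220), 100)  # strides 1.1, 1.1
#' @export
stride_times <- function(hs, sampling_rate) {
  if (length(hs) < 2L) gf_data_error("need at least 2 heel strikes, got %d", length(hs))
  if (is.unsorted(hs, strictly = TRUE)) gf_data_error("heel-strike indices must be strictly increasing")
  st <- diff(hs) / sampling_rate
  list(per_stride = st, mean = mean(st))
}

#' Per-stride lengths from heel-strike indices and walking speed
#'
#' Stride length = stride time (s) x walking speed (m/s); the spatial
#' reconstruction used when only timing and average speed are known.
#'
#' @inheritParams stride_times
#' @param speed walking speed, m/s (> 0).
#' @return list with `per_stride` (meters) and `mean`.
#' @export
stride_lengths <- function(hs, sampling_rate, speed) {
  if (!is_number(speed) || speed <= 0) gf_param_error("speed must be > 0")
  st <- stride_times(hs, sampling_rate)
  list(per_stride = st$per_stride * speed, mean = st$mean * speed)
}

#' Per-stride stance phases
#'
#' For each stride `[HS_n, HS_{n+1})` the stance phase is
#' `(TO* - HS_n) / (HS_{n+1} - HS_n) x 100`, where `TO*` is the unique
#' toe-off falling inside that stride. The pairing covers both recording
#' conventions: when the first toe-off precedes the first heel strike it is
#' simply ignored (it belongs to an unobserved stride), and the indexing
#' shifts accordingly.
#'
#' @param hs,to strictly increasing heel-strike / toe-off sample indices.
#' @param sampling_rate Hz (unused in the percentage, kept for interface
#'   symmetry).
#' @return list with `per_stride` (percent) and `mean`.
#' @examples
#' stance_phases(c(0, 120), c(72), 100)  # 60%
#' @export
stance_phases <- function(hs, to, sampling_rate = NULL) {
  if (length(hs) < 2L) gf_data_error("need at least 2 heel strikes, got %d", length(hs))
  if (is.unsorted(hs, strictly = TRUE) || is.unsorted(to, strictly = TRUE)) {
    gf_data_error("event indices must be strictly increasing")
  }
  n_strides <- length(hs) - 1L
  phases <- numeric(n_strides)
  for (i in seq_len(n_strides)) {
    inside <- to[to > hs[i] & to < hs[i + 1L]]
    if (length(inside) != 1L) {
      gf_data_error("stride %d contains %d toe-offs (expected exactly 1)", i, length(inside))
    }
    phases[i] <- (inside - hs[i]) / (hs[i + 1L] - hs[i]) * 100
  }
  list(per_stride = phases, mean = mean(phases))
}

#' Gait asymmetry from per-side mean swing times
#'
#' `GA = |ln(shorter mean swing / longer mean swing)| x 100`; 0 for perfectly
#' symmetric gait, order-invariant in its arguments.
#'
#' @param swing_left_mean,swing_right_mean mean swing times, seconds (> 0).
#' @return gait asymmetry in percent.
#' @examples
#' gait_asymmetry(0.38, 0.42)  # ~10.01
#' @export
gait_asymmetry <- function(swing_left_mean, swing_right_mean) {
  if (!is_number(swing_left_mean) || swing_left_mean <= 0 ||
      !is_number(swing_right_mean) || swing_right_mean <= 0) {
    gf_param_error("swing time means must be > 0")
  }
  s <- min(swing_left_mean, swing_right_mean)
  l <- max(swing_left_mean, swing_right_mean)
  abs(log(s / l)) * 100
}

#' Normalize a value by body height
#'
#' Walking speed and stride length are commonly divided by participant height
#' to remove stature effects.
#'
#' @param value numeric value(s).
#' @param height height in meters (> 0).
#' @return value / height.
#' @export
normalize_by_height <- function(value, height) {
  if (!is_number(height) || height <= 0) gf_param_error("height must be > 0")
  value / height
}

#' Extract the nine spatiotemporal gait variables from an event series
#'
#' Works on a trimmed (steady-state) two-foot [event_series()]. Walking
#' duration is the span from the first to the last heel strike across feet;
#' the step count is the number of heel strikes across both feet minus one
#' (the first heel strike opens the window);
#' stride-level metrics are pooled over both feet; gait asymmetry compares
#' the per-side mean swing times.
#'
#' @param events trimmed [event_series()] with both feet.
#' @param walkway_distance distance covered by the retained strides, meters.
#' @param height participant height in meters (for the normalized variants).
#' @param cv_per_foot compute the CVs per foot and average them instead of
#'   pooling strides across feet (default pooled).
#' @param population_sd use population SD in the CVs.
#' @return a one-row data frame of class `gait_features` with the nine gait
#'   variables plus height-normalized walking speed and stride length.
#' @export
extract_features <- function(events, walkway_distance = 20, height = 1.6,
                             cv_per_foot = FALSE, population_sd = FALSE) {
  if (!inherits(events, "event_series")) gf_param_error("events must be an event_series")
  sides <- names(events$hs)
  if (!setequal(sides, c("left", "right"))) {
    gf_data_error("extract_features needs events for both feet")
  }
  fs <- events$sampling_rate
  all_hs <- sort(c(events$hs$left, events$hs$right))
  duration <- (all_hs[length(all_hs)] - all_hs[1]) / fs
  if (duration <= 0) gf_data_error("degenerate event series: zero walking duration")
  speed <- walking_speed(walkway_distance, duration)
  # the first heel strike opens the window; each later one completes a step
  cad <- cadence(length(all_hs) - 1L, duration)

  per_side <- lapply(c(left = "left", right = "right"), function(s) {
    st <- stride_times(events$hs[[s]], fs)
    sp <- stance_phases(events$hs[[s]], events$to[[s]], fs)
    sl <- stride_lengths(events$hs[[s]], fs, speed)
    swing <- st$per_stride * (1 - sp$per_stride / 100)
    list(st = st, sp = sp, sl = sl, swing_mean = mean(swing))
  })
  pooled <- function(get) c(get(per_side$left), get(per_side$right))
  cv_of <- function(get) {
    if (cv_per_foot) {
      mean(c(coefficient_of_variation(get(per_side$left), population_sd),
             coefficient_of_variation(get(per_side$right), population_sd)))
    } else {
      coefficient_of_variation(pooled(get), population_sd)
    }
  }
  st_all <- pooled(function(x) x$st$per_stride)
  sp_all <- pooled(function(x) x$sp$per_stride)
  sl_all <- pooled(function(x) x$sl$per_stride)
  zero_var <- function(x) isTRUE(all.equal(stats::sd(x), 0))
  safe_cv <- function(get, values) if (zero_var(values)) 0 else cv_of(get)
  out <- data.frame(
    walking_speed = speed,
    stride_length = mean(sl_all),
    cadence = cad,
    stance_phase = mean(sp_all),
    stride_time = mean(st_all),
    cv_stride_length = safe_cv(function(x) x$sl$per_stride, sl_all),
    cv_stance_phase = safe_cv(function(x) x$sp$per_stride, sp_all),
    cv_stride_time = safe_cv(function(x) x$st$per_stride, st_all),
    gait_asymmetry = gait_asymmetry(per_side$left$swing_mean, per_side$right$swing_mean),
    walking_speed_norm = normalize_by_height(speed, height),
    stride_length_norm = normalize_by_height(mean(sl_all), height)
  )
  class(out) <- c("gait_features", class(out))
  out
}
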