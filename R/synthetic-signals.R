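#' Plan for a simulated walk
#'
#' Describes one pass over a walkway: how many steady strides, their timing
#' statistics, the stance fraction, walking speed, an optional left/right
#' swing-time offset (asymmetry injection), and the number of non-steady
#' (acceleration/deceleration) strides prepended and appended. Defaults match
#' a typical older-adult preferred-speed walk recorded at 100 Hz.
#'
#' @param n_strides number of steady-state strides per foot (>= 2).
#' @param stride_time_mean,stride_time_sd stride time mean and stride-to-stride
#'   SD, seconds.
#' @param stance_fraction stance phase as a fraction of the stride (0-1).
#' @param walking_speed mean forward speed, m/s.
#' @param left_right_swing_offset seconds added to the right swing time and
#'   removed from the left (total bilateral swing difference); 0 = symmetric.
#' @param n_transient_strides strides of acceleration at the start and of
#'   deceleration at the end (each), with linearly ramped stride times.
#' @param sampling_rate Hz.
#' @param noise_sd additive Gaussian noise on the acceleration channels, g.
#' @param seed integer RNG seed.
#' @return an object of class `gait_plan`.
#' @export
gait_plan <- function(n_strides = 10L,
                      stride_time_mean = 1.0,
                      stride_time_sd = 0.02,
                      stance_fraction = 0.58,
                      walking_speed = 1.2,
                      left_right_swing_offset = 0,
                      n_transient_strides = 2L,
                      sampling_rate = 100,
                      noise_sd = 0.02,
                      seed = 1L) {
  if (!is_count(n_strides, min = 2L)) gf_param_error("n_strides must be an integer >= 2")
  if (!is_number(stride_time_mean) || stride_time_mean <= 0) {
    gf_param_error("stride_time_mean must be > 0")
  }
  if (!is_number(stride_time_sd) || stride_time_sd < 0) gf_param_error("stride_time_sd must be >= 0")
  if (!is_number(stance_fraction) || stance_fraction <= 0 || stance_fraction >= 1) {
    gf_param_error("stance_fraction must lie strictly between 0 and 1")
  }
  if (!is_number(walking_speed) || walking_speed <= 0) gf_param_error("walking_speed must be > 0")
  if (!is_number(left_right_swing_offset)) gf_param_error("left_right_swing_offset must be a number")
  if (!is_count(n_transient_strides)) gf_param_error("n_transient_strides must be a non-negative integer")
  if (!is_number(sampling_rate) || sampling_rate <= 0) gf_param_error("sampling_rate must be > 0")
  if (!is_number(noise_sd) || noise_sd < 0) gf_param_error("noise_sd must be >= 0")
  if (!is_count(abs(seed))) gf_param_error("seed must be an integer")
  swing <- stride_time_mean * (1 - stance_fraction)
  if (abs(left_right_swing_offset) / 2 >= swing) {
    gf_param_error("left_right_swing_offset too large for the planned swing time")
  }
  structure(list(
    n_strides = as.integer(n_strides), stride_time_mean = stride_time_mean,
    stride_time_sd = stride_time_sd, stance_fraction = stance_fraction,
    walking_speed = walking_speed, left_right_swing_offset = left_right_swing_offset,
    n_transient_strides = as.integer(n_transient_strides),
    sampling_rate = sampling_rate, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "gait_plan")
}

#' Raw per-foot IMU recording
#'
#' Tri-axial acceleration (g, clipped to +-6) and angular velocity (deg/s,
#' clipped to +-500) sampled at a fixed rate, matching shoe-mounted data
#' loggers. All channels have equal length and `time` increases in steps of
#' `1/sampling_rate`.
#'
#' @param side `"left"` or `"right"`.
#' @param time time stamps, seconds.
#' @param accel_ap,accel_vert,accel_ml anteroposterior, vertical, mediolateral
#'   acceleration, g.
#' @param gyro_x,gyro_y,gyro_z angular velocity, deg/s.
#' @param sampling_rate Hz.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(side, time, accel_ap, accel_vert, accel_ml,
                          gyro_x, gyro_y, gyro_z, sampling_rate) {
  side <- match.arg(side, c("left", "right"))
  lens <- lengths(list(time, accel_ap, accel_vert, accel_ml, gyro_x, gyro_y, gyro_z))
  if (length(unique(lens)) != 1L) gf_data_error("all IMU channels must have equal length")
  clip <- function(x, lim) pmin(pmax(x, -lim), lim)
  structure(list(
    side = side, time = time,
    accel_ap = clip(accel_ap, 6), accel_vert = clip(accel_vert, 6),
    accel_ml = clip(accel_ml, 6),
    gyro_x = clip(gyro_x, 500), gyro_y = clip(gyro_y, 500), gyro_z = clip(gyro_z, 500),
    sampling_rate = sampling_rate
  ), class = "imu_recording")
}

# Per-side event schedule in seconds. Transient strides ramp linearly from
# ramp_factor x mean down to the drawn steady stride times (acceleration) and
# back up (deceleration). Returns HS times, TO times and steady stride flags.
plan_side_schedule <- function(plan, stride_times, swing_delta, t0) {
  nt <- plan$n_transient_strides
  ramp_in <- if (nt > 0) plan$stride_time_mean * seq(1.3, 1.0, length.out = nt + 1L)[1:nt] else numeric(0)
  ramp_out <- if (nt > 0) plan$stride_time_mean * seq(1.0, 1.3, length.out = nt + 1L)[-1] else numeric(0)
  all_strides <- c(ramp_in, stride_times, ramp_out)
  steady <- c(rep(FALSE, nt), rep(TRUE, plan$n_strides), rep(FALSE, nt))
  hs <- t0 + cumsum(c(0, all_strides))
  swing <- all_strides * (1 - plan$stance_fraction) + swing_delta
  to <- hs[-length(hs)] + (all_strides - swing)      # stance duration after HS
  list(hs = hs, to = to, steady = steady)
}

# Gaussian pulse train evaluated on a regular time grid.
pulse_train <- function(time, centers, amplitude, width_sd) {
  y <- numeric(length(time))
  for (tc in centers) {
    idx <- which(abs(time - tc) <= 6 * width_sd)
    y[idx] <- y[idx] + amplitude * exp(-((time[idx] - tc)^2) / (2 * width_sd^2))
  }
  y
}

#' Simulate a pair of IMU walking recordings with known events
#'
#' Heel strikes are planted as Gaussian pulses (about 50 ms wide) on the
#' anteroposterior acceleration channel and toe-offs on the vertical channel,
#' riding on a low-amplitude sinusoidal gait baseline, so that the per-cycle
#' acceleration-maximum detection rule recovers exactly the planted events.
#' Event times are snapped to the sample grid; the returned ground truth holds
#' the planted sample indices, per-event steady flags, and the steady-state
#' window.
#'
#' @param plan a [gait_plan()].
#' @return list with `left` and `right` [imu_recording()]s and `ground_truth`
#'   (per-side `hs`, `to`, `hs_steady`, `to_steady`, plus `steady_start`,
#'   `steady_end` sample indices and the planted per-side swing-time means).
#' @export
simulate_imu_walk <- function(plan) {
  if (!inherits(plan, "gait_plan")) gf_param_error("plan must be a gait_plan")
  fs <- plan$sampling_rate
  set.seed(plan$seed)
  draw_strides <- function() {
    st <- stats::rnorm(plan$n_strides, plan$stride_time_mean, plan$stride_time_sd)
    pmax(st, 0.3 * plan$stride_time_mean)
  }
  off <- plan$left_right_swing_offset / 2
  left_sched <- plan_side_schedule(plan, draw_strides(), swing_delta = -off, t0 = 0.5)
  right_sched <- plan_side_schedule(plan, draw_strides(), swing_delta = +off,
                                    t0 = 0.5 + plan$stride_time_mean / 2)
  t_end <- max(left_sched$hs, right_sched$hs, left_sched$to, right_sched$to) + 0.5
  n <- ceiling(t_end * fs) + 1L
  time <- (seq_len(n) - 1L) / fs

  snap <- function(tt) as.integer(round(tt * fs)) + 1L   # 1-based sample indices
  gt <- list(
    hs = list(left = snap(left_sched$hs), right = snap(right_sched$hs)),
    to = list(left = snap(left_sched$to), right = snap(right_sched$to)),
    hs_steady = list(left = c(left_sched$steady, FALSE) | c(FALSE, left_sched$steady),
                     right = c(right_sched$steady, FALSE) | c(FALSE, right_sched$steady)),
    to_steady = list(left = left_sched$steady, right = right_sched$steady),
    swing_mean = list(
      left = mean(diff(left_sched$hs)[left_sched$steady] * (1 - plan$stance_fraction) - off),
      right = mean(diff(right_sched$hs)[right_sched$steady] * (1 - plan$stance_fraction) + off)
    )
  )
  steady_hs_all <- c(gt$hs$left[gt$hs_steady$left], gt$hs$right[gt$hs_steady$right])
  gt$steady_start <- min(steady_hs_all)
  gt$steady_end <- max(steady_hs_all)

  # Cycle phase locked to an event schedule: phase is integer exactly at the
  # events and extends linearly half a stride beyond each end, so the baseline
  # sinusoid peaks exactly at the planted events and nowhere else.
  cycle_phase <- function(event_times) {
    k <- seq_along(event_times) - 1L
    dt <- mean(diff(event_times))
    knots_t <- c(event_times[1] - dt / 2, event_times, event_times[length(event_times)] + dt / 2)
    knots_p <- c(-0.5, k, k[length(k)] + 0.5)
    stats::approx(knots_t, knots_p, xout = time, rule = 2)$y
  }
  make_side <- function(side, sched) {
    hs_t <- (snap(sched$hs) - 1L) / fs            # pulse centers on the grid
    to_t <- (snap(sched$to) - 1L) / fs
    f0 <- 1 / plan$stride_time_mean
    base_ap <- 0.15 * cos(2 * pi * cycle_phase(hs_t))
    base_vt <- 0.15 * cos(2 * pi * cycle_phase(to_t))
    ap <- base_ap + pulse_train(time, hs_t, amplitude = 1.0, width_sd = 0.02)
    vt <- 1 + base_vt + pulse_train(time, to_t, amplitude = 0.8, width_sd = 0.02)
    ml <- 0.1 * sin(pi * f0 * time)
    gx <- 60 * sin(2 * pi * f0 * time)
    gy <- 30 * cos(2 * pi * f0 * time)
    gz <- 10 * sin(pi * f0 * time)
    if (plan$noise_sd > 0) {
      ap <- ap + stats::rnorm(n, 0, plan$noise_sd)
      vt <- vt + stats::rnorm(n, 0, plan$noise_sd)
      ml <- ml + stats::rnorm(n, 0, plan$noise_sd)
      gx <- gx + stats::rnorm(n, 0, plan$noise_sd * 100)
      gy <- gy + stats::rnorm(n, 0, plan$noise_sd * 100)
      gz <- gz + stats::rnorm(n, 0, plan$noise_sd * 100)
    }
    imu_recording(side, time, ap, vt, ml, gx, gy, gz, fs)
  }
  list(left = make_side("left", left_sched),
       right = make_side("right", right_sched),
       ground_truth = gt)
}

#' Write / read an IMU recording as CSV (plus JSON sidecar)
#'
#' Columns: `time_s, accel_ap_g, accel_vert_g, accel_ml_g, gyro_x_dps,
#' gyro_y_dps, gyro_z_dps`. The sidecar (`<path>.json`) stores the sampling
#' rate, the side, and — for synthetic data — the planted ground truth.
#'
#' @param recording an [imu_recording()].
#' @param path CSV file path.
#' @param ground_truth optional ground-truth list to embed in the sidecar.
#' @return `write_imu_csv` returns `path` invisibly; `read_imu_csv` returns a
#'   list with `recording` and (if present) `ground_truth`.
#' @export
write_imu_csv <- function(recording, path, ground_truth = NULL) {
  d <- data.frame(
    time_s = recording$time,
    accel_ap_g = recording$accel_ap, accel_vert_g = recording$accel_vert,
    accel_ml_g = recording$accel_ml,
    gyro_x_dps = recording$gyro_x, gyro_y_dps = recording$gyro_y,
    gyro_z_dps = recording$gyro_z
  )
  utils::write.csv(d, path, row.names = FALSE)
  side <- list(sampling_rate = recording$sampling_rate, side = recording$side)
  if (!is.null(ground_truth)) side$ground_truth <- ground_truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "accel_ap_g", "accel_vert_g", "accel_ml_g",
            "gyro_x_dps", "gyro_y_dps", "gyro_z_dps")
  if (!all(need %in% names(d))) {
    gf_schema_error("IMU CSV missing columns: %s", paste(setdiff(need, names(d)), collapse = ", "))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) gf_schema_error("missing sidecar JSON %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  rec <- imu_recording(meta$side, d$time_s, d$accel_ap_g, d$accel_vert_g, d$accel_ml_g,
                       d$gyro_x_dps, d$gyro_y_dps, d$gyro_z_dps, meta$sampling_rate)
  list(recording = rec, ground_truth = meta$ground_truth)
}
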