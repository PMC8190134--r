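# Shared fixtures: everything is generated in code, no stored data.

# A deterministic zero-noise walk with known stride structure.
zero_noise_walk <- function(n_strides = 10L, stride_time = 1.0, stance = 0.6,
                            speed = 1.2, swing_offset = 0, seed = 1L) {
  simulate_imu_walk(gait_plan(
    n_strides = n_strides, stride_time_mean = stride_time, stride_time_sd = 0,
    stance_fraction = stance, walking_speed = speed,
    left_right_swing_offset = swing_offset, noise_sd = 0, seed = seed
  ))
}

# Detect, trim the planted transients, and merge both feet.
detect_and_trim <- function(walk, trim = 2L) {
  merge_event_series(
    trim_transients(detect_events(walk$left), trim, trim),
    trim_transients(detect_events(walk$right), trim, trim)
  )
}

# Distribution table where both groups share every marginal except overrides.
# overrides: named list variable -> c(high_mean, low_mean) (shared sd = sd).
flat_dist_table <- function(overrides = list(), sd = 0.1) {
  d <- default_dist_table()
  base <- tapply(d$mean, d$variable, mean)
  d$mean <- base[d$variable]
  d$sd <- sd
  for (v in names(overrides)) {
    d$mean[d$variable == v & d$group == "high"] <- overrides[[v]][1]
    d$mean[d$variable == v & d$group == "low"] <- overrides[[v]][2]
  }
  d
}

# Small cohort for classifier tests.
small_cohort <- function(n = 200L, seed = 1L, dist = default_dist_table(), ...) {
  simulate_cohort(cohort_spec(n_participants = n, p_high_risk = 0.4, dist = dist,
                              exact_stratification = TRUE, seed = seed, ...))
}

# Brute-force AUC by pair counting (independent of the rank-based route).
auc_brute_force <- function(scores, labels) {
  y <- as.integer(labels %in% c(1, "high"))
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
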