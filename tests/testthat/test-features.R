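test_that("walking_speed and cadence follow their definitions", {
  expect_equal(walking_speed(20, 20), 1.0)
  expect_equal(walking_speed(20, 16.67), 20 / 16.67)
  expect_error(walking_speed(20, 0), class = "gaitfall_parameter_error")
  expect_equal(cadence(30, 18), 100.0)
  expect_equal(cadence(0, 12), 0)
  expect_equal(cadence(40, 20), 120.0)
  expect_error(cadence(10, -1), class = "gaitfall_parameter_error")
})

test_that("stride times and lengths come from heel-strike differences", {
  st <- stride_times(c(0, 110, 220), 100)
  expect_equal(st$per_stride, c(1.1, 1.1))
  expect_equal(st$mean, 1.1)
  expect_equal(stride_times(c(0, 100), 100)$mean, 1.0)
  expect_error(stride_times(c(0), 100), class = "gaitfall_data_error")

  expect_equal(stride_lengths(c(0, 110), 100, 1.2)$per_stride, 1.32)
  expect_equal(stride_lengths(c(0, 122), 100, 0.9)$per_stride, 1.098)
  expect_error(stride_lengths(c(0, 110), 100, 0), class = "gaitfall_parameter_error")
})

test_that("stance phases pair each stride with its unique interior toe-off", {
  expect_equal(stance_phases(c(0, 120), c(72))$per_stride, 60.0)
  expect_equal(stance_phases(c(0, 100), c(50))$per_stride, 50.0)
  expect_equal(stance_phases(c(0, 100, 200), c(60, 160))$per_stride, c(60, 60))
  # a leading toe-off (recording started mid-stance) is ignored
  expect_equal(stance_phases(c(100, 200, 300), c(40, 160, 260))$per_stride, c(60, 60))
  expect_error(stance_phases(c(0, 100, 200), c(60)), class = "gaitfall_data_error")
  expect_error(stance_phases(c(0, 200), c(60, 160)), class = "gaitfall_data_error")
})

test_that("gait asymmetry is the absolute log swing ratio, order-invariant", {
  expect_equal(gait_asymmetry(0.40, 0.40), 0)
  expect_equal(gait_asymmetry(0.38, 0.42), abs(log(38 / 42)) * 100)
  expect_equal(gait_asymmetry(0.38, 0.42), 10.01, tolerance = 1e-3)
  expect_equal(gait_asymmetry(0.42, 0.38), gait_asymmetry(0.38, 0.42))
  expect_error(gait_asymmetry(0, 0.4), class = "gaitfall_parameter_error")
})

test_that("coefficient of variation uses the sample SD and is scale invariant", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1.0, 1.1, 1.2)), 0.1 / 1.1 * 100)
  x <- c(0.9, 1.05, 1.1, 0.98)
  expect_equal(coefficient_of_variation(3.1 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), class = "gaitfall_undefined_value_error")
  expect_equal(coefficient_of_variation(c(1, 2, 3), population = TRUE),
               sqrt(2 / 3) / 2 * 100)
})

test_that("normalize_by_height divides by height", {
  expect_equal(normalize_by_height(1.2, 1.60), 0.75)
  expect_equal(normalize_by_height(0.83, 1.0), 0.83)
  expect_equal(normalize_by_height(1.5, 1.5), 1.0)
  expect_error(normalize_by_height(1, 0), class = "gaitfall_parameter_error")
})

test_that("equation evaluations match a brute-force oracle on random event sets", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    hs <- cumsum(c(0, sample(80:140, n, replace = TRUE)))
    stance_frac <- runif(1, 0.5, 0.7)
    to <- round(hs[-length(hs)] + stance_frac * diff(hs))
    fs <- 100
    # oracle: explicit per-stride loops, no shared code with the package
    n_str <- length(hs) - 1
    o_st <- o_sp <- numeric(n_str)
    for (i in seq_len(n_str)) {
      o_st[i] <- (hs[i + 1] - hs[i]) / fs
      o_sp[i] <- (to[i] - hs[i]) / (hs[i + 1] - hs[i]) * 100
    }
    expect_equal(stride_times(hs, fs)$per_stride, o_st)
    expect_equal(stance_phases(hs, to)$per_stride, o_sp)
    speed <- runif(1, 0.8, 1.6)
    expect_equal(stride_lengths(hs, fs, speed)$per_stride, o_st * speed)
    expect_equal(coefficient_of_variation(o_st), sd(o_st) / mean(o_st) * 100)
  }
})

test_that("zero-noise symmetric walks yield zero variability and asymmetry", {
  w <- zero_noise_walk(n_strides = 10, stride_time = 1.0, stance = 0.6, speed = 1.2)
  ev <- detect_and_trim(w)
  dur <- (max(unlist(ev$hs)) - min(unlist(ev$hs))) / 100
  f <- extract_features(ev, walkway_distance = 1.2 * dur, height = 1.6)
  expect_equal(f$cv_stride_length, 0)
  expect_equal(f$cv_stance_phase, 0)
  expect_equal(f$cv_stride_time, 0)
  expect_equal(f$gait_asymmetry, 0)
  expect_equal(f$stride_time, 1.0, tolerance = 0.011)       # 1-sample quantization
  expect_equal(f$stance_phase, 60, tolerance = 1.1)
  expect_equal(f$cadence, 120, tolerance = 0.5)
  expect_equal(f$walking_speed, 1.2)
  expect_equal(f$walking_speed_norm, 1.2 / 1.6)
  # definitional consistency on periodic input
  expect_equal(f$stride_length * f$cadence / 120, f$walking_speed, tolerance = 0.01)
  # stance + swing partition per stride
  expect_equal(f$stance_phase + (1 - f$stance_phase / 100) * 100, 100)
})

test_that("planted stride-time variability is recovered at 200 strides", {
  w <- simulate_imu_walk(gait_plan(n_strides = 200, stride_time_mean = 1.0,
                                   stride_time_sd = 0.02, noise_sd = 0, seed = 6))
  ev <- detect_and_trim(w)
  dur <- (max(unlist(ev$hs)) - min(unlist(ev$hs))) / 100
  f <- extract_features(ev, walkway_distance = 1.2 * dur, height = 1.6)
  planted_cv <- 2.0
  se <- planted_cv / sqrt(2 * 400)    # pooled strides across both feet
  # quantization adds ~0.29-sample noise per event on top of the planted CV
  expect_lt(abs(f$cv_stride_time - planted_cv), 3 * se + 0.15)
})

test_that("a planted swing offset reproduces the expected gait asymmetry", {
  w <- zero_noise_walk(n_strides = 30, stride_time = 1.0, stance = 0.6,
                       swing_offset = 0.04, seed = 8)
  ev <- detect_and_trim(w)
  dur <- (max(unlist(ev$hs)) - min(unlist(ev$hs))) / 100
  f <- extract_features(ev, walkway_distance = 1.2 * dur, height = 1.6)
  expect_equal(f$gait_asymmetry, abs(log(0.38 / 0.42)) * 100, tolerance = 0.15)
})

test_that("extract_features validates its inputs", {
  w <- zero_noise_walk(n_strides = 6)
  one_foot <- trim_transients(detect_events(w$left), 2, 2)
  expect_error(extract_features(one_foot), class = "gaitfall_data_error")
  expect_error(extract_features(detect_and_trim(w), height = -1),
               class = "gaitfall_parameter_error")
})
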