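#' Low-pass filter specification
#'
#' Butterworth low-pass design used throughout the pipeline. The defaults
#' (second order, 10 Hz cutoff, zero-phase forward-backward application) are
#' the standard pre-processing for 100 Hz shoe-mounted IMU gait signals:
#' gait-relevant accelerations live below ~10 Hz and zero-phase application
#' preserves event timing (a single-pass IIR filter would lag every peak).
#'
#' @param order filter order (>= 1). Zero-phase application doubles the
#'   effective attenuation order.
#' @param cutoff -3 dB cutoff frequency in Hz; must be below Nyquist at the
#'   sampling rate the filter is applied with.
#' @param zero_phase apply the filter forward and backward (no phase lag).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2L, cutoff = 10, zero_phase = TRUE) {
  if (!is_count(order, min = 1L)) gf_param_error("filter order must be a positive integer")
  if (!is_number(cutoff) || cutoff <= 0) gf_param_error("cutoff must be a positive frequency in Hz")
  if (!is_flag(zero_phase)) gf_param_error("zero_phase must be TRUE or FALSE")
  structure(list(order = as.integer(order), cutoff = cutoff, zero_phase = zero_phase),
            class = "filter_spec")
}

# Polynomial coefficients (descending powers) from roots, kept real.
poly_from_roots <- function(roots) {
  coefs <- 1 + 0i
  for (r in roots) coefs <- c(coefs, 0i) - r * c(0i, coefs)
  Re(coefs)
}

# Digital Butterworth low-pass via bilinear transform with frequency
# prewarping. Returns list(b, a) with a[1] == 1 and unit DC gain.
butter_lowpass <- function(order, cutoff, sampling_rate) {
  if (cutoff >= sampling_rate / 2) {
    gf_param_error("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                   cutoff, sampling_rate / 2)
  }
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p_analog <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * sampling_rate * tan(pi * cutoff / sampling_rate)
  p_analog <- warped * p_analog
  fs2 <- 2 * sampling_rate
  p_digital <- (fs2 + p_analog) / (fs2 - p_analog)
  a <- poly_from_roots(p_digital)
  b <- poly_from_roots(rep(-1 + 0i, order))     # zeros at z = -1
  b <- b * (sum(a) / sum(b))                    # DC gain 1
  list(b = b, a = a)
}

# Single-pass direct-form IIR with zero initial conditions, C-speed via
# stats::filter (convolution for the MA part, recursion for the AR part).
iir_filter <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb:(nb + length(x) - 1)])
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Apply a Butterworth low-pass filter to a signal
#'
#' Zero-phase (forward-backward) application is the default; the signal is
#' extended at both ends by odd reflection before filtering so that edge
#' transients from the zero initial conditions decay inside the padding.
#'
#' @param series numeric signal vector.
#' @param sampling_rate sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered signal, same length as the input.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' lowpass(sin(2 * pi * 1 * t), 100, filter_spec())
#' @export
lowpass <- function(series, sampling_rate, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) gf_param_error("spec must be a filter_spec")
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    gf_param_error("sampling_rate must be a positive number")
  }
  n <- length(series)
  if (n <= 3L * spec$order) gf_data_error("series too short for filter order %d", spec$order)
  ba <- butter_lowpass(spec$order, spec$cutoff, sampling_rate)
  if (!spec$zero_phase) return(iir_filter(series, ba$b, ba$a))
  # odd-reflection padding; ~3 cutoff periods lets startup transients decay
  padlen <- min(n - 1L, max(3L * length(ba$a), ceiling(3 * sampling_rate / spec$cutoff)))
  head_ext <- 2 * series[1] - series[(padlen + 1L):2L]
  tail_ext <- 2 * series[n] - series[(n - 1L):(n - padlen)]
  y <- iir_filter(c(head_ext, series, tail_ext), ba$b, ba$a)
  y <- rev(iir_filter(rev(y), ba$b, ba$a))
  y[(padlen + 1L):(padlen + n)]
}

# Local maxima of x separated by at least min_sep samples; taller peaks win.
find_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0L || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Dominant gait-cycle length in samples from the autocorrelation of the
# (demeaned) signal, searched over physiologic stride times (0.4-2.5 s).
dominant_cycle_lag <- function(x, sampling_rate) {
  lo <- max(2L, floor(0.4 * sampling_rate))
  hi <- min(length(x) - 2L, ceiling(2.5 * sampling_rate))
  if (hi <= lo) gf_data_error("recording shorter than one expected gait cycle")
  ac <- stats::acf(x, lag.max = hi, plot = FALSE, demean = TRUE)$acf[-1]
  lo + which.max(ac[lo:hi]) - 1L
}

#' Construct an event series
#'
#' Holds heel-strike (HS) and toe-off (TO) sample indices per foot. Within
#' each foot the indices are strictly increasing and between two consecutive
#' heel strikes there is at most one toe-off.
#'
#' @param hs named list with integer vectors `left` and/or `right`.
#' @param to named list with integer vectors `left` and/or `right`.
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `event_series`.
#' @export
event_series <- function(hs, to, sampling_rate) {
  for (side in names(hs)) {
    h <- hs[[side]]; t <- to[[side]]
    if (is.unsorted(h, strictly = TRUE) || is.unsorted(t, strictly = TRUE)) {
      gf_data_error("event indices must be strictly increasing (%s side)", side)
    }
    if (length(h) >= 2L) {
      counts <- findInterval(t, h)
      inner <- counts[counts >= 1L & counts < length(h)]
      if (anyDuplicated(inner)) {
        gf_data_error("more than one toe-off between consecutive heel strikes (%s side)", side)
      }
    }
  }
  structure(list(hs = hs, to = to, sampling_rate = sampling_rate), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  for (side in names(x$hs)) {
    cat(sprintf("%s: %d heel strikes, %d toe-offs\n",
                side, length(x$hs[[side]]), length(x$to[[side]])))
  }
  invisible(x)
}

#' Detect heel-strike and toe-off events from a filtered IMU recording
#'
#' Heel strikes are the per-cycle maxima of the low-pass-filtered
#' anteroposterior acceleration; toe-offs the per-cycle maxima of the filtered
#' vertical acceleration. "One per cycle" is operationalized as a minimum peak
#' separation of `min_cycle_fraction` times the dominant autocorrelation lag
#' of the anteroposterior channel. Supernumerary toe-offs between two heel
#' strikes are discarded, keeping the largest.
#'
#' @param recording an [imu_recording()].
#' @param spec a [filter_spec()].
#' @param min_cycle_fraction minimum peak separation as a fraction of the
#'   estimated cycle length (default 0.5).
#' @param min_relative_height peaks whose height above the channel median is
#'   below this fraction of the tallest peak's height are discarded; this is
#'   scale-invariant and suppresses numerical ripple from the filter around
#'   quiet segments (default 0.25).
#' @return an [event_series()] with the recording's side populated.
#' @export
detect_events <- function(recording, spec = filter_spec(), min_cycle_fraction = 0.5,
                          min_relative_height = 0.25) {
  if (!inherits(recording, "imu_recording")) gf_param_error("recording must be an imu_recording")
  if (!is_number(min_cycle_fraction) || min_cycle_fraction <= 0 || min_cycle_fraction >= 1) {
    gf_param_error("min_cycle_fraction must lie in (0, 1)")
  }
  fs <- recording$sampling_rate
  ap <- recording$accel_ap
  vt <- recording$accel_vert
  if (stats::sd(ap) == 0) gf_detection_error("no maxima found on the anteroposterior channel")
  if (stats::sd(vt) == 0) gf_detection_error("no maxima found on the vertical channel")
  ap_f <- lowpass(ap, fs, spec)
  vt_f <- lowpass(vt, fs, spec)
  lag <- dominant_cycle_lag(ap_f, fs)
  sep <- max(2L, floor(min_cycle_fraction * lag))
  prune <- function(peaks, x) {
    if (length(peaks) == 0L) return(peaks)
    height <- x[peaks] - stats::median(x)
    peaks[height >= min_relative_height * max(height)]
  }
  hs <- prune(find_peaks(ap_f, sep), ap_f)
  to <- prune(find_peaks(vt_f, sep), vt_f)
  if (length(hs) == 0L) gf_detection_error("no maxima found on the anteroposterior channel")
  if (length(to) == 0L) gf_detection_error("no maxima found on the vertical channel")
  to <- enforce_alternation(hs, to, vt_f)
  side <- recording$side
  ev <- list(left = integer(0), right = integer(0))
  hs_l <- ev; hs_l[[side]] <- hs
  to_l <- ev; to_l[[side]] <- to
  out <- event_series(hs = hs_l[side], to = to_l[side], sampling_rate = fs)
  out
}

# Keep at most one TO per HS-to-HS interval (largest amplitude), and at most
# one TO before the first HS / after the last HS (the nearest).
enforce_alternation <- function(hs, to, amplitude) {
  if (length(hs) < 1L || length(to) == 0L) return(to)
  bin <- findInterval(to, hs)
  kept <- integer(0)
  for (b in unique(bin)) {
    members <- to[bin == b]
    if (b == 0L) {
      kept <- c(kept, members[length(members)])       # nearest before first HS
    } else if (b == length(hs)) {
      kept <- c(kept, members[1L])                    # nearest after last HS
    } else {
      kept <- c(kept, members[which.max(amplitude[members])])
    }
  }
  sort(kept)
}

#' Drop acceleration and deceleration strides from an event series
#'
#' Gait tests on a finite walkway start and end with non-steady strides; the
#' first `n_start` and last `n_end` heel-strike-to-heel-strike cycles are
#' removed per side, together with their interior toe-offs, so that features
#' are computed on steady-state gait only.
#'
#' @param events an [event_series()].
#' @param n_start,n_end number of strides to drop at each end (default 2).
#' @return trimmed [event_series()].
#' @export
trim_transients <- function(events, n_start = 2L, n_end = 2L) {
  if (!inherits(events, "event_series")) gf_param_error("events must be an event_series")
  if (!is_count(n_start) || !is_count(n_end)) {
    gf_param_error("n_start and n_end must be non-negative integers")
  }
  if (n_start == 0L && n_end == 0L) return(events)
  hs <- events$hs; to <- events$to
  for (side in names(hs)) {
    h <- hs[[side]]
    n_strides <- length(h) - 1L
    if (n_strides - n_start - n_end < 2L) {
      gf_data_error("too few strides on the %s side: %d strides, trimming %d + %d leaves < 2",
                    side, n_strides, n_start, n_end)
    }
    h <- h[(n_start + 1L):(length(h) - n_end)]
    hs[[side]] <- h
    to[[side]] <- to[[side]][to[[side]] > h[1L] & to[[side]] < h[length(h)]]
  }
  event_series(hs = hs, to = to, sampling_rate = events$sampling_rate)
}

#' Merge single-side event series from the two feet
#'
#' @param left,right [event_series()] objects carrying the left and right foot.
#' @return combined [event_series()].
#' @export
merge_event_series <- function(left, right) {
  if (left$sampling_rate != right$sampling_rate) {
    gf_data_error("sampling rates differ between feet")
  }
  event_series(hs = list(left = left$hs$left, right = right$hs$right),
               to = list(left = left$to$left, right = right$to$right),
               sampling_rate = left$sampling_rate)
}

#' Write / read detected events as CSV
#'
#' Long format: columns `side`, `event_type` (`hs`/`to`), `sample_index`,
#' `time_s`.
#'
#' @param events an [event_series()].
#' @param path CSV file path.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   returns an [event_series()].
#' @export
write_events_csv <- function(events, path) {
  rows <- do.call(rbind, lapply(names(events$hs), function(side) {
    rbind(
      data.frame(side = side, event_type = "hs", sample_index = events$hs[[side]]),
      data.frame(side = side, event_type = "to", sample_index = events$to[[side]])
    )
  }))
  rows$time_s <- (rows$sample_index - 1L) / events$sampling_rate
  rows <- rows[order(rows$side, rows$event_type, rows$sample_index), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param sampling_rate sampling rate in Hz (not stored in the CSV itself).
#' @export
read_events_csv <- function(path, sampling_rate) {
  d <- utils::read.csv(path)
  need <- c("side", "event_type", "sample_index")
  if (!all(need %in% names(d))) gf_schema_error("events CSV must have columns %s",
                                                paste(need, collapse = ", "))
  sides <- unique(d$side)
  hs <- lapply(sides, function(s) sort(d$sample_index[d$side == s & d$event_type == "hs"]))
  to <- lapply(sides, function(s) sort(d$sample_index[d$side == s & d$event_type == "to"]))
  names(hs) <- sides; names(to) <- sides
  event_series(hs = hs, to = to, sampling_rate = sampling_rate)
}
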