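# Breath-level preprocessing: temporal alignment and resampling, zero-phase
# Butterworth low-pass filtering, exhalation segmentation, conversion to the
# volume domain, and piecewise aggregate approximation (PAA) to a fixed
# length.

#' Align and resample a raw record onto a uniform grid
#'
#' CO2 and flow are linearly interpolated onto a shared uniform time grid.
#' Endpoints are clamped to the record's own time range, so no extrapolation
#' occurs.
#'
#' @param raw A `raw_record`.
#' @param rate Target sampling rate (Hz); default 200.
#' @return An `aligned_record`: list with `rate`, `t0`, `co2`, `flow`.
#' @export
align_resample <- function(raw, rate = 200) {
  stopifnot(inherits(raw, "raw_record"))
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  if (nrow(raw) < 8L) {
    stopf("alignment needs at least 8 samples, got %d", nrow(raw))
  }
  dur <- raw$t[nrow(raw)] - raw$t[1]
  if (dur < 0.1) stopf("record duration %.3f s is too short (< 0.1 s)", dur)
  grid <- seq(raw$t[1], raw$t[nrow(raw)], by = 1 / rate)
  co2 <- stats::approx(raw$t, raw$co2, xout = grid, rule = 2)$y
  flow <- stats::approx(raw$t, raw$flow, xout = grid, rule = 2)$y
  structure(list(rate = rate, t0 = raw$t[1], co2 = co2, flow = flow,
                 subject_id = attr(raw, "subject_id"),
                 label = attr(raw, "label")),
            class = "aligned_record")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass of the given order forward and backward
#' (zero phase, so phase II/III slopes are not phase-distorted). The squared
#' magnitude response doubles the attenuation in dB; DC gain is 1. Both the
#' CO2 and flow channels are filtered.
#'
#' @param rec An `aligned_record`.
#' @param order Filter order; default 3.
#' @param cutoff_hz Cutoff frequency (Hz); must be below the Nyquist rate.
#' @return The filtered `aligned_record`.
#' @export
lowpass_filter <- function(rec, order = 3, cutoff_hz = 10) {
  stopifnot(inherits(rec, "aligned_record"))
  if (cutoff_hz >= rec$rate / 2) {
    stopf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
          cutoff_hz, rec$rate / 2)
  }
  bf <- signal::butter(order, cutoff_hz / (rec$rate / 2), type = "low")
  pad <- ceiling(3 * rec$rate / cutoff_hz)
  rec$co2 <- .filtfilt_padded(bf, rec$co2, pad)
  rec$flow <- .filtfilt_padded(bf, rec$flow, pad)
  rec
}

# Forward-backward filtering with odd-reflection end extension, so the
# start-up transient of the zero-initial-condition filter is absorbed in
# the padding rather than the signal (DC gain stays 1 at the edges).
.filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  p <- min(n - 1L, as.integer(pad))
  ext <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- as.numeric(signal::filter(bf, ext))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(p + 1):(p + n)]
}

#' Segment exhalations from an aligned record
#'
#' Exhalations are maximal runs where flow exceeds `flow_threshold`. Each
#' run is trimmed to start at the last CO2 trough at or before the run onset
#' and to end at the CO2 peak (end-tidal point) within the run. Runs shorter
#' than `min_len` samples or with a CO2 rise below `min_rise` are discarded
#' as invalid breaths.
#'
#' @param rec An `aligned_record`.
#' @param flow_threshold Flow level (L/s) defining exhalation; default 0.02.
#' @param min_len Minimum segment length in samples; default 16.
#' @param min_rise Minimum CO2 rise (%) within a valid breath; default 1.0.
#' @return A list of `breath_segment`s (`start_idx`, `end_idx`), possibly
#'   empty.
#' @export
segment_exhalations <- function(rec, flow_threshold = 0.02, min_len = 16L,
                                min_rise = 1.0) {
  stopifnot(inherits(rec, "aligned_record"))
  on <- rec$flow > flow_threshold
  if (!any(on)) return(list())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  prev_end <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) { prev_end <- ends[i]; next }
    s <- starts[i]; e <- ends[i]
    # end at the end-tidal CO2 peak inside the run
    e2 <- s + which.max(rec$co2[s:e]) - 1L
    # walk back from the run onset to the last CO2 trough before it
    s2 <- s
    floor_idx <- max(prev_end + 1L, 1L)
    while (s2 > floor_idx && rec$co2[s2 - 1L] <= rec$co2[s2]) s2 <- s2 - 1L
    prev_end <- ends[i]
    if (e2 - s2 + 1L < min_len) next
    if (diff(range(rec$co2[s2:e2])) < min_rise) next
    segs[[length(segs) + 1L]] <-
      structure(list(start_idx = s2, end_idx = e2), class = "breath_segment")
  }
  segs
}

#' Convert one exhalation to the volume domain
#'
#' Cumulative exhaled volume is the trapezoidal integral of flow over time
#' from the segment start (converted to mL); the CO2 concentration is
#' carried over per sample, yielding the volumetric capnogram for that
#' breath. Negative flow samples inside the segment are clipped to zero with
#' a warning.
#'
#' @param rec An `aligned_record`.
#' @param seg A `breath_segment` within `rec`.
#' @return A `vcap_curve`: list with `volume` (mL, non-decreasing, starting
#'   at 0) and `co2` (%).
#' @export
to_volume_domain <- function(rec, seg) {
  stopifnot(inherits(rec, "aligned_record"), inherits(seg, "breath_segment"))
  idx <- seg$start_idx:seg$end_idx
  if (seg$start_idx < 1L || seg$end_idx > length(rec$flow)) {
    stopf("segment [%d, %d] outside record of length %d",
          seg$start_idx, seg$end_idx, length(rec$flow))
  }
  flow <- rec$flow[idx]
  if (any(flow < 0)) {
    warning("negative flow inside exhalation segment clipped to 0",
            call. = FALSE)
    flow[flow < 0] <- 0
  }
  dt <- 1 / rec$rate
  n <- length(flow)
  # cumulative trapezoid, L -> mL
  vol <- 1000 * dt * c(0, cumsum((flow[-n] + flow[-1]) / 2))
  structure(list(volume = vol, co2 = rec$co2[idx],
                 subject_id = rec$subject_id, label = rec$label),
            class = "vcap_curve")
}

#' Piecewise aggregate approximation to a fixed length
#'
#' For an input of length `n >= m`, sample `j` of the output is the mean of
#' the input over frame `j`, where the `m` frames partition `[0, n)` with
#' exact width `n/m`; samples straddling a frame boundary contribute
#' fractionally, so no sample is dropped. For `n < m` the series is linearly
#' interpolated up to length `m`.
#'
#' @param x Numeric vector (a `vcap_curve`'s CO2 channel, volume-ordered) or
#'   a `vcap_curve`.
#' @param m Output length; default 224.
#' @return A `paa_series`: numeric vector of length `m` with attribute
#'   `source_length`.
#' @export
paa_reduce <- function(x, m = 224L) {
  meta <- NULL
  if (inherits(x, "vcap_curve")) {
    meta <- list(subject_id = x$subject_id, label = x$label)
    x <- x$co2
  }
  n <- length(x)
  if (n < 2L) stopf("PAA needs at least 2 samples, got %d", n)
  check_number(m, "m", lower = 1)
  m <- as.integer(m)
  if (n >= m) {
    w <- n / m
    out <- numeric(m)
    for (j in seq_len(m)) {
      a <- (j - 1) * w            # frame covers [a, b) in sample coordinates
      b <- j * w
      i0 <- floor(a) + 1L
      i1 <- ceiling(b)
      i1 <- min(i1, n)
      idx <- i0:i1
      wt <- pmin(idx, b) - pmax(idx - 1, a)
      out[j] <- sum(x[idx] * wt) / w
    }
  } else {
    out <- stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
  }
  structure(out, class = "paa_series", source_length = n,
            subject_id = meta$subject_id, label = meta$label)
}

#' Full preprocessing pipeline for one raw record
#'
#' Composition of [align_resample()], [lowpass_filter()],
#' [segment_exhalations()], [to_volume_domain()] and [paa_reduce()]: one
#' fixed-length volumetric-capnogram series per valid breath in the record.
#'
#' @param raw A `raw_record`.
#' @param rate Resampling rate (Hz).
#' @param order,cutoff_hz Butterworth filter settings.
#' @param flow_threshold,min_len,min_rise Segmentation gates; see
#'   [segment_exhalations()].
#' @param m PAA output length; default 224.
#' @return A list of `paa_series`, empty when the record holds no valid
#'   breath.
#' @export
preprocess_record <- function(raw, rate = 200, order = 3, cutoff_hz = 10,
                              flow_threshold = 0.02, min_len = 16L,
                              min_rise = 1.0, m = 224L) {
  rec <- lowpass_filter(align_resample(raw, rate), order, cutoff_hz)
  segs <- segment_exhalations(rec, flow_threshold, min_len, min_rise)
  lapply(segs, function(s) paa_reduce(to_volume_domain(rec, s), m))
}
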