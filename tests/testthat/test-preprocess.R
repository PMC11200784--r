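# Alignment/resampling, filtering, segmentation, volume conversion and PAA.

test_that("resampling preserves uniform input and exact linear signals", {
  t <- seq(0, 1, by = 1 / 200)
  rec <- raw_record(t, co2 = sin(t), flow = rep(0.5, length(t)))
  al <- align_resample(rec, 200)
  expect_equal(al$co2, sin(t), tolerance = 1e-9)
  expect_equal(al$rate, 200)

  t80 <- seq(0, 1, by = 1 / 80)
  al2 <- align_resample(raw_record(t80, co2 = rep(5, length(t80)),
                                   flow = rep(0.1, length(t80))), 200)
  expect_equal(al2$co2, rep(5, length(al2$co2)), tolerance = 1e-12)

  t50 <- seq(0, 1, by = 1 / 50)
  al3 <- align_resample(raw_record(t50, co2 = t50, flow = rep(0.1, 51)), 200)
  grid <- seq(0, 1, by = 1 / 200)
  expect_equal(al3$co2, grid, tolerance = 1e-9)

  short <- raw_record(seq(0, 0.05, length.out = 10), co2 = 1:10 / 10,
                      flow = rep(0.1, 10))
  expect_error(align_resample(short), "too short")
})

test_that("Butterworth filtering has unit DC gain and the analytic roll-off", {
  n <- 801
  t <- seq(0, 4, length.out = n)
  const <- aligned_from(rep(5, n), rep(5, n))
  out <- lowpass_filter(const, 3, 10)
  expect_equal(out$co2, rep(5, n), tolerance = 1e-6)

  mid <- 201:600  # central window, away from edge transients
  # stop band: 50 Hz sinusoid; two-pass analytic magnitude (1+(50/10)^6)^-1
  s50 <- aligned_from(sin(2 * pi * 50 * t), rep(0, n))
  a50 <- max(abs(lowpass_filter(s50, 3, 10)$co2[mid]))
  expect_lt(a50, 0.01)
  expect_lt(a50, 2 * (1 + (50 / 10)^6)^-1)

  # pass band: 1 Hz sinusoid barely attenuated
  s1 <- aligned_from(sin(2 * pi * 1 * t), rep(0, n))
  a1 <- max(abs(lowpass_filter(s1, 3, 10)$co2[mid]))
  expect_gt(a1, 0.99)
  expect_lt(a1, 1.01)

  expect_error(lowpass_filter(const, 3, 100), "Nyquist")
})

test_that("segmentation finds exhalations and rejects degenerate records", {
  p <- grade_morphology("normal")
  p$noise_sd <- 0
  rec <- simulate_breath(p, seed = 1)
  al <- lowpass_filter(align_resample(rec))
  segs <- segment_exhalations(al)
  expect_length(segs, 1)
  # covers at least 90% of the known exhale window
  expect_lt((segs[[1]]$end_idx - segs[[1]]$start_idx + 1) /
              length(al$co2), 1.01)
  expect_gt((segs[[1]]$end_idx - segs[[1]]$start_idx + 1) /
              length(al$co2), 0.90)

  none <- aligned_from(stats::runif(400, 0, 0.2), rep(0, 400))
  expect_length(segment_exhalations(none), 0)

  # two breaths separated by a zero-flow gap
  two <- aligned_from(c(al$co2, rep(0, 50), al$co2),
                      c(al$flow, rep(0, 50), al$flow))
  expect_length(segment_exhalations(two), 2)
})

test_that("volume conversion is a trapezoidal integral of flow", {
  n <- 201
  rec <- aligned_from(rep(5, n), rep(1, n))  # 1 L/s for 1 s at 200 Hz
  seg <- structure(list(start_idx = 1L, end_idx = n), class = "breath_segment")
  vc <- to_volume_domain(rec, seg)
  expect_equal(vc$volume[1], 0)
  expect_lt(abs(max(vc$volume) - 1000) / 1000, 0.005)
  expect_true(all(diff(vc$volume) >= 0))

  zero <- aligned_from(rep(5, n), rep(0, n))
  expect_true(all(to_volume_domain(zero, seg)$volume == 0))

  dbl <- aligned_from(rep(5, n), rep(2, n))
  expect_equal(max(to_volume_domain(dbl, seg)$volume),
               2 * max(vc$volume))

  neg <- aligned_from(rep(5, n), c(rep(1, 100), rep(-0.5, 101)))
  expect_warning(vneg <- to_volume_domain(neg, seg), "clipped")
  expect_true(all(diff(vneg$volume) >= 0))
})

test_that("PAA frame means match the fractional-boundary oracle", {
  expect_equal(as.numeric(paa_reduce(c(1, 2, 3, 4), 2)), c(1.5, 3.5))
  expect_equal(as.numeric(paa_reduce(c(1, 2, 3), 2)), c(4 / 3, 8 / 3),
               tolerance = 1e-12)
  expect_equal(as.numeric(paa_reduce(rep(2.5, 1000), 224)), rep(2.5, 224),
               tolerance = 1e-12)
  expect_length(paa_reduce(1:5, 224), 224)
  expect_error(paa_reduce(1, 4), "at least 2")

  # independent oracle: weighted frame means at a fractional width
  paa_oracle <- function(x, m) {
    n <- length(x)
    w <- n / m
    vapply(seq_len(m), function(j) {
      lo <- (j - 1) * w
      hi <- j * w
      wt <- pmax(0, pmin(seq_len(n), hi) - pmax(seq_len(n) - 1, lo))
      sum(wt * x) / w
    }, numeric(1))
  }
  for (case in list(c(7, 3), c(10, 4), c(13, 5), c(224, 224))) {
    x <- sin(seq_len(case[1]))
    expect_equal(as.numeric(paa_reduce(x, case[2])),
                 paa_oracle(x, case[2]), tolerance = 1e-12)
  }
})

test_that("PAA preserves the global mean on exact frames and monotonicity", {
  x <- withr::with_seed(4, stats::rnorm(448))  # 448 = 2 * 224
  expect_equal(mean(as.numeric(paa_reduce(x, 224))), mean(x),
               tolerance = 1e-9)
  mono <- cumsum(abs(x))
  expect_true(all(diff(as.numeric(paa_reduce(mono, 224))) >= 0))
  expect_true(all(diff(as.numeric(paa_reduce(mono[1:100], 224))) >= 0))
})

test_that("the composed pipeline yields fixed-length series deterministically", {
  rec <- clean_breath("GOLD2", noise_sd = 0.05, seed = 6)
  out <- preprocess_record(rec)
  expect_gte(length(out), 1)
  expect_true(all(vapply(out, length, integer(1)) == 224))
  expect_identical(preprocess_record(rec), out)

  n <- 400
  silent <- raw_record(seq(0, 2, length.out = n), co2 = rep(0.1, n),
                       flow = rep(0, n))
  expect_length(preprocess_record(silent), 0)
})

test_that("exhaled volume is invariant to the device sampling rate", {
  p <- grade_morphology("GOLD1")
  p$noise_sd <- 0
  final_vol <- function(rate) {
    p$sample_rate <- rate
    rec <- simulate_breath(p, seed = 1)
    al <- lowpass_filter(align_resample(rec))
    seg <- segment_exhalations(al)[[1]]
    max(to_volume_domain(al, seg)$volume)
  }
  v80 <- final_vol(80)
  v200 <- final_vol(200)
  expect_lt(abs(v80 - v200) / v200, 0.01)

  # and the encoded series agree closely between device rates
  p$sample_rate <- 80
  s80 <- preprocess_record(simulate_breath(p, seed = 1))[[1]]
  p$sample_rate <- 200
  s200 <- preprocess_record(simulate_breath(p, seed = 1))[[1]]
  expect_gt(stats::cor(as.numeric(s80), as.numeric(s200)), 0.999)
})
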