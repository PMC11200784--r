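# Synthetic three-phase capnogram generator.

test_that("grade morphology orders phase II/III features by severity", {
  grades <- vcap_grades()
  slopes <- vapply(grades, function(g) grade_morphology(g)$phase3_slope,
                   numeric(1))
  steeps <- vapply(grades, function(g) grade_morphology(g)$phase2_steepness,
                   numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_true(all(diff(steeps) < 0))
  expect_error(grade_morphology("GOLD9"), "GOLD9")
  expect_error(grade_morphology(3), "3")
})

test_that("breath parameter invariants are enforced", {
  expect_error(breath_params(dead_space_volume = 600, tidal_volume = 500),
               "tidal_volume")
  expect_error(breath_params(etco2 = 0), "etco2")
  expect_error(breath_params(etco2 = 12), "etco2")
  expect_error(breath_params(phase3_slope = -1), "phase3_slope")
  expect_error(breath_params(noise_sd = -0.1), "noise_sd")
  expect_error(breath_params(sample_rate = 0), "sample_rate")
})

test_that("simulated flow is a half-sine integrating to the tidal volume", {
  for (grade in c("normal", "GOLD2", "GOLD4")) {
    rec <- clean_breath(grade)
    expect_true(all(rec$flow >= 0))
    # trapezoidal quadrature oracle, L -> mL
    dt <- diff(rec$t)
    vol <- 1000 * sum(dt * (rec$flow[-1] + rec$flow[-nrow(rec)]) / 2)
    expect_lt(abs(vol - 500) / 500, 0.01)
  }
})

test_that("noise-free CO2 shows the three-phase morphology", {
  for (grade in c("normal", "GOLD4")) {
    p <- grade_morphology(grade)
    p$noise_sd <- 0
    rec <- simulate_breath(p, seed = 1)
    dt <- diff(rec$t)
    vol <- 1000 * c(0, cumsum(dt * (rec$flow[-1] + rec$flow[-nrow(rec)]) / 2))
    # phase I: near-zero CO2 over the first half of the dead space
    ph1 <- vol < 0.5 * p$dead_space_volume
    expect_true(any(ph1))
    expect_true(all(rec$co2[ph1] < 0.05 * p$etco2))
    # non-decreasing up to the end-tidal point
    expect_true(all(diff(rec$co2) >= -1e-9))
    # end-tidal value reaches etco2
    expect_equal(max(rec$co2), p$etco2, tolerance = 1e-3)
  }
})

test_that("least squares on the plateau recovers the phase III slope within 5%", {
  for (grade in vcap_grades()) {
    p <- grade_morphology(grade)
    p$noise_sd <- 0
    rec <- simulate_breath(p, seed = 1)
    est <- fit_phase3_slope(rec, p)
    expect_lt(abs(est - p$phase3_slope) / p$phase3_slope, 0.05)
  }
})

test_that("identical parameters and seed reproduce the record exactly", {
  p <- grade_morphology("GOLD2")
  a <- simulate_breath(p, seed = 42)
  b <- simulate_breath(p, seed = 42)
  expect_identical(a, b)
  d <- simulate_breath(p, seed = 43)
  expect_false(identical(a$co2, d$co2))
})

test_that("cohort counts, labels and class balance follow the configuration", {
  cfg <- cohort_config(n_per_class = 5, class_set = c("normal", "GOLD1"),
                       breaths_per_subject = 3, seed = 9)
  ch <- simulate_cohort(cfg)
  expect_equal(length(unique(ch$manifest$subject_id)), 10)
  expect_equal(nrow(ch$manifest), 30)
  expect_equal(length(ch$records), 30)
  subj <- ch$manifest[!duplicated(ch$manifest$subject_id), ]
  expect_equal(unname(table(subj$grade)), rep(5L, 2), ignore_attr = TRUE)
  # one label per subject; normal grade maps to normal label, rest to COPD
  expect_true(all(subj$label[subj$grade == "normal"] == "normal"))
  expect_true(all(subj$label[subj$grade != "normal"] == "COPD"))
})

test_that("cohort simulation is reproducible and seed-sensitive", {
  cfg <- cohort_config(n_per_class = 3, class_set = c("normal", "GOLD3"),
                       breaths_per_subject = 2, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$records, b$records)
  cfg2 <- cohort_config(n_per_class = 3, class_set = c("normal", "GOLD3"),
                        breaths_per_subject = 2, seed = 8)
  expect_false(identical(simulate_cohort(cfg2)$records, a$records))
})

test_that("mean estimated phase III slope increases strictly with severity", {
  means <- vapply(vcap_grades(), function(grade) {
    ch <- simulate_cohort(cohort_config(n_per_class = 5, class_set = grade,
                                        breaths_per_subject = 1, seed = 21))
    base <- grade_morphology(grade)
    ests <- vapply(ch$records, function(rec) {
      fit_phase3_slope(rec, base)
    }, numeric(1))
    mean(ests)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
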