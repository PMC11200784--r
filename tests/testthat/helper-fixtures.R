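# In-code fixtures shared across test files.

# Deterministic pseudo-random grayscale image of a given side.
rand_image <- function(side = 16L, seed = 1L, kind = "GASF", label = NULL) {
  px <- matrix(floor(((seq_len(side^2) * 2654435761) %% (2^16)) / 2^16 * 256),
               side)
  px <- (px + seed * 37) %% 256
  gray_image(px, kind = kind, label = label)
}

# One clean synthetic exhalation record for a grade, noise-free by default.
clean_breath <- function(grade = "normal", noise_sd = 0, seed = 1L,
                         sample_rate = 80) {
  p <- grade_morphology(grade)
  p$noise_sd <- noise_sd
  p$sample_rate <- sample_rate
  simulate_breath(p, seed = seed)
}

# Aligned record built directly from channel vectors at a uniform rate.
aligned_from <- function(co2, flow, rate = 200) {
  structure(list(rate = rate, t0 = 0, co2 = co2, flow = flow,
                 subject_id = NULL, label = NULL),
            class = "aligned_record")
}

# Least-squares phase III slope (CO2 % per L) of a noise-free record.
fit_phase3_slope <- function(rec, params) {
  al <- align_resample(rec)
  seg <- segment_exhalations(al)[[1]]
  vc <- to_volume_domain(al, seg)
  v0 <- params$dead_space_volume + log(99) / params$phase2_steepness
  sel <- vc$volume > v0
  unname(stats::coef(stats::lm(vc$co2[sel] ~ vc$volume[sel]))[2] * 1000)
}

# Bare pixel matrix of a gray image, metadata attributes stripped.
px <- function(img) matrix(as.integer(img), nrow(img))
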