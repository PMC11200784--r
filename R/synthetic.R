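# Synthetic volumetric capnogram generator.
#
# One exhalation is modelled in the volume domain with the classic
# three-phase morphology: phase I (anatomical dead space, near-zero CO2),
# phase II (sigmoid ascending branch as airway and alveolar gas mix) and
# phase III (alveolar plateau with a finite slope). Airway obstruction
# shallows phase II (slower washout of dead-space gas) and steepens the
# phase III slope (ventilation inhomogeneity), so severity grades map to a
# decreasing sigmoid steepness and an increasing plateau slope.

#' Severity grades recognised by the simulator
#'
#' @return Character vector `c("normal", "GOLD1", "GOLD2", "GOLD3", "GOLD4")`.
#' @export
vcap_grades <- function() c("normal", "GOLD1", "GOLD2", "GOLD3", "GOLD4")

#' Breath morphology parameters
#'
#' Bundle of physiological parameters describing one synthetic exhalation.
#'
#' @param dead_space_volume Anatomical dead-space volume (mL); exhaled first,
#'   carrying almost no CO2.
#' @param tidal_volume Exhaled tidal volume (mL); must exceed the dead space.
#' @param etco2 End-tidal CO2 concentration (%), the plateau end value.
#' @param phase2_steepness Sigmoid slope of the phase II ascending branch
#'   (per mL of exhaled volume); larger is steeper.
#' @param phase3_slope Slope of the alveolar plateau (CO2 % per L).
#' @param exhale_duration Duration of the exhalation (s).
#' @param noise_sd Standard deviation of additive Gaussian device noise
#'   (CO2 %).
#' @param sample_rate Device sampling rate (Hz).
#'
#' @return An object of class `breath_params` (a named list).
#' @export
breath_params <- function(dead_space_volume = 150, tidal_volume = 500,
                          etco2 = 5.2, phase2_steepness = 0.25,
                          phase3_slope = 0.4, exhale_duration = 2.5,
                          noise_sd = 0.05, sample_rate = 80) {
  check_number(dead_space_volume, "dead_space_volume", lower = 0, strict_lower = TRUE)
  check_number(tidal_volume, "tidal_volume",
               lower = dead_space_volume, strict_lower = TRUE)
  check_number(etco2, "etco2", lower = 0, upper = 10, strict_lower = TRUE)
  check_number(phase2_steepness, "phase2_steepness", lower = 0, strict_lower = TRUE)
  check_number(phase3_slope, "phase3_slope", lower = 0)
  check_number(exhale_duration, "exhale_duration", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (etco2 <= phase3_slope * tidal_volume / 1000) {
    stopf("phase3_slope %g %%/L is too steep for etco2 %g over %g mL (CO2 would go negative)",
          phase3_slope, etco2, tidal_volume)
  }
  structure(list(
    dead_space_volume = dead_space_volume, tidal_volume = tidal_volume,
    etco2 = etco2, phase2_steepness = phase2_steepness,
    phase3_slope = phase3_slope, exhale_duration = exhale_duration,
    noise_sd = noise_sd, sample_rate = sample_rate
  ), class = "breath_params")
}

# Baseline morphology per grade. phase3_slope strictly increases and
# phase2_steepness strictly decreases with severity.
.grade_table <- list(
  normal = list(phase2_steepness = 0.250, phase3_slope = 0.4, etco2 = 5.2),
  GOLD1  = list(phase2_steepness = 0.180, phase3_slope = 1.2, etco2 = 5.4),
  GOLD2  = list(phase2_steepness = 0.130, phase3_slope = 2.0, etco2 = 5.6),
  GOLD3  = list(phase2_steepness = 0.090, phase3_slope = 2.8, etco2 = 5.8),
  GOLD4  = list(phase2_steepness = 0.065, phase3_slope = 3.6, etco2 = 6.0)
)

#' Baseline breath morphology for a severity grade
#'
#' Deterministic mapping from a severity label to [breath_params()]. The
#' phase III slope strictly increases and the phase II steepness strictly
#' decreases from `normal` to `GOLD4`, the two features of the volumetric
#' capnogram that track airway obstruction.
#'
#' @param grade One of [vcap_grades()].
#' @return A `breath_params` object.
#' @export
#' @examples
#' grade_morphology("normal")$phase3_slope
#' grade_morphology("GOLD4")$phase3_slope
grade_morphology <- function(grade) {
  if (!is.character(grade) || length(grade) != 1L || !grade %in% names(.grade_table)) {
    stopf("unknown grade '%s'; expected one of %s",
          paste(as.character(grade), collapse = ","),
          paste(vcap_grades(), collapse = ", "))
  }
  g <- .grade_table[[grade]]
  breath_params(phase2_steepness = g$phase2_steepness,
                phase3_slope = g$phase3_slope, etco2 = g$etco2)
}

# Noise-free CO2 concentration (%) at cumulative exhaled volume v (mL):
# a sigmoid centred at the dead-space volume gates a plateau line that
# reaches etco2 at end-tidal volume with slope phase3_slope (% per L).
.co2_of_volume <- function(v, p) {
  gate <- 1 / (1 + exp(-p$phase2_steepness * (v - p$dead_space_volume)))
  plateau <- p$etco2 - p$phase3_slope * (p$tidal_volume - v) / 1000
  gate * plateau
}

#' Simulate one exhalation
#'
#' Generates a raw device record (time, CO2 %, expiratory flow) for a single
#' breath. Flow is a non-negative half-sine whose integral equals the tidal
#' volume; noise-free CO2 follows the three-phase volume-domain model (near
#' zero over the dead space, sigmoid ascent centred at the dead-space volume,
#' linear plateau with the configured slope); i.i.d. Gaussian noise of
#' standard deviation `noise_sd` is added to the CO2 channel.
#'
#' @param params A [breath_params()] object.
#' @param seed Integer seed; identical `params` + `seed` give an identical
#'   record.
#' @return A `raw_record`: data frame with columns `t` (s), `co2` (%),
#'   `flow` (L/s).
#' @export
simulate_breath <- function(params, seed = 1L) {
  stopifnot(inherits(params, "breath_params"))
  p <- params
  t <- seq(0, p$exhale_duration, by = 1 / p$sample_rate)
  # half-sine flow; amplitude set so the time integral is the tidal volume
  amp <- pi * p$tidal_volume / (2000 * p$exhale_duration)    # L/s
  flow <- amp * sin(pi * t / p$exhale_duration)
  flow[flow < 0] <- 0
  # analytic cumulative volume of the half-sine, in mL
  vol <- p$tidal_volume / 2 * (1 - cos(pi * t / p$exhale_duration))
  co2 <- .co2_of_volume(vol, p)
  if (p$noise_sd > 0) {
    co2 <- co2 + with_seed(seed, stats::rnorm(length(co2), 0, p$noise_sd))
  }
  raw_record(t = t, co2 = co2, flow = flow)
}

#' Cohort configuration for the simulator
#'
#' @param n_per_class Number of subjects simulated for each class label.
#' @param class_set Character vector of labels, a subset of [vcap_grades()].
#' @param breaths_per_subject Number of breath records per subject.
#' @param seed Integer master seed for the cohort.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_class = 20,
                          class_set = c("normal", "GOLD2"),
                          breaths_per_subject = 3, seed = 1L) {
  check_number(n_per_class, "n_per_class", lower = 1)
  check_number(breaths_per_subject, "breaths_per_subject", lower = 1)
  check_number(seed, "seed")
  class_set <- as.character(class_set)
  bad <- setdiff(class_set, vcap_grades())
  if (length(bad)) stopf("unknown grade '%s'", bad[[1]])
  if (anyDuplicated(class_set)) stopf("class_set contains duplicates")
  structure(list(n_per_class = as.integer(n_per_class), class_set = class_set,
                 breaths_per_subject = as.integer(breaths_per_subject),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Lognormal jitter with a given coefficient of variation, unit median.
.jitter <- function(n, cv) exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))

#' Simulate a labelled cohort
#'
#' Draws `n_per_class` subjects per class; each subject's morphology is the
#' grade baseline from [grade_morphology()] jittered multiplicatively
#' (lognormal, 10% coefficient of variation) so classes overlap mildly but
#' remain separable. Each subject contributes `breaths_per_subject` records.
#'
#' @param cfg A [cohort_config()].
#' @return A `vcap_cohort`: list with `manifest` (data frame with columns
#'   `subject_id`, `label`, `grade`, `record_path`) and `records` (named list
#'   of `raw_record` data frames keyed by record id).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  manifest <- list()
  records <- list()
  with_seed(cfg$seed, {
    sid <- 0L
    for (grade in cfg$class_set) {
      base <- grade_morphology(grade)
      label <- if (grade == "normal") "normal" else "COPD"
      for (i in seq_len(cfg$n_per_class)) {
        sid <- sid + 1L
        subject_id <- sprintf("S%03d", sid)
        j <- .jitter(5L, 0.10)
        p <- breath_params(
          dead_space_volume = base$dead_space_volume * j[1],
          tidal_volume = max(base$tidal_volume * j[2],
                             base$dead_space_volume * j[1] * 1.5),
          etco2 = min(base$etco2 * j[3], 9.9),
          phase2_steepness = base$phase2_steepness * j[4],
          phase3_slope = base$phase3_slope * j[5],
          exhale_duration = base$exhale_duration,
          noise_sd = base$noise_sd, sample_rate = base$sample_rate
        )
        for (b in seq_len(cfg$breaths_per_subject)) {
          rec_id <- sprintf("%s_b%02d", subject_id, b)
          rec <- simulate_breath(p, seed = sample.int(.Machine$integer.max, 1L))
          attr(rec, "subject_id") <- subject_id
          attr(rec, "label") <- label
          records[[rec_id]] <- rec
          manifest[[length(manifest) + 1L]] <- data.frame(
            subject_id = subject_id, label = label, grade = grade,
            record_path = paste0(rec_id, ".csv"), stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  structure(list(manifest = do.call(rbind, manifest), records = records),
            class = "vcap_cohort")
}

#' @export
print.vcap_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic capnogram cohort: %d subjects, %d records\n",
              length(unique(m$subject_id)), nrow(m)))
  print(table(grade = m$grade[!duplicated(m$subject_id)]))
  invisible(x)
}
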