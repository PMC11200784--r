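# File formats: raw record CSV (`t,co2,flow`), cohort manifest CSV,
# 8-bit grayscale PNG, and the YAML/JSON run configuration.

#' Construct a validated raw record
#'
#' @param t Sample times (s), strictly increasing.
#' @param co2 CO2 concentration (%).
#' @param flow Expiratory flow (L/s).
#' @param subject_id,label Optional metadata carried as attributes.
#' @return A `raw_record` data frame with columns `t`, `co2`, `flow`.
#' @export
raw_record <- function(t, co2, flow, subject_id = NULL, label = NULL) {
  if (length(t) != length(co2) || length(t) != length(flow)) {
    stopf("t, co2 and flow must have equal length")
  }
  if (length(t) < 2L) stopf("a raw record needs at least 2 samples, got %d", length(t))
  if (!all(is.finite(t)) || !all(is.finite(co2)) || !all(is.finite(flow))) {
    stopf("raw record contains non-finite values")
  }
  if (any(diff(t) <= 0)) stopf("time column must be strictly increasing")
  out <- data.frame(t = as.numeric(t), co2 = as.numeric(co2),
                    flow = as.numeric(flow))
  class(out) <- c("raw_record", "data.frame")
  attr(out, "subject_id") <- subject_id
  attr(out, "label") <- label
  out
}

#' Read a raw record CSV
#'
#' Expects a header `t,co2,flow` (seconds, CO2 %, L/s) and validates the
#' time column for strict monotonicity.
#'
#' @param path Path to the CSV file.
#' @return A `raw_record` data frame.
#' @export
read_raw_record <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  missing <- setdiff(c("t", "co2", "flow"), names(df))
  if (length(missing)) {
    stopf("raw record %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  raw_record(df$t, df$co2, df$flow)
}

#' Write a raw record CSV
#'
#' @param rec A `raw_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_record <- function(rec, path) {
  stopifnot(inherits(rec, "raw_record"))
  utils::write.csv(as.data.frame(rec)[c("t", "co2", "flow")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a grayscale image
#'
#' @param pixels Integer matrix of intensities in \[0, 255\], square.
#' @param kind `"GASF"` or `"GADF"`.
#' @param subject_id,label Optional metadata attributes.
#' @return A `gray_image`: integer matrix with attributes.
#' @export
gray_image <- function(pixels, kind = c("GASF", "GADF"),
                       subject_id = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    stopf("pixels must be a square matrix")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stopf("pixel intensities must lie in [0, 255]")
  }
  if (any(pixels != round(pixels))) stopf("pixel intensities must be integers")
  structure(matrix(as.integer(pixels), nrow(pixels)),
            class = "gray_image", kind = kind,
            subject_id = subject_id, label = label)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("%s grayscale image %dx%d, intensity range [%d, %d]\n",
              attr(x, "kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Display a grayscale image
#'
#' @param x A `gray_image`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gray_image <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "", ylab = "", main = attr(x, "kind"), ...)
  invisible(x)
}

#' Write an 8-bit grayscale PNG
#'
#' Single-channel, lossless; reading the file back recovers the pixel matrix
#' exactly. The encoder settings are fixed so identical inputs produce
#' byte-identical files.
#'
#' @param img A [gray_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' @param path Path to a single-channel PNG written by [write_gray_png()].
#' @param kind Image kind recorded on the returned object.
#' @return A `gray_image`.
#' @export
read_gray_png <- function(path, kind = "GASF") {
  m <- png::readPNG(path)
  if (length(dim(m)) != 2L) stopf("%s is not a single-channel grayscale PNG", path)
  gray_image(round(m * 255), kind = kind)
}

#' Write a cohort to disk
#'
#' Writes one raw-record CSV per breath plus a `manifest.csv` with columns
#' `subject_id,label,grade,record_path`.
#'
#' @param cohort A `vcap_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vcap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$records)) {
    write_raw_record(cohort$records[[id]], file.path(dir, paste0(id, ".csv")))
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a cohort from disk
#'
#' @param dir Directory containing `manifest.csv` and the record CSVs.
#' @return A `vcap_cohort`.
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stopf("no manifest.csv under %s", dir)
  manifest <- utils::read.csv(mp, colClasses = "character")
  need <- c("subject_id", "label", "grade", "record_path")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stopf("manifest is missing column(s): %s",
                             paste(missing, collapse = ", "))
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- read_raw_record(file.path(dir, manifest$record_path[i]))
    attr(rec, "subject_id") <- manifest$subject_id[i]
    attr(rec, "label") <- manifest$label[i]
    records[[sub("\\.csv$", "", manifest$record_path[i])]] <- rec
  }
  structure(list(manifest = manifest, records = records), class = "vcap_cohort")
}

# Known run-configuration keys with defaults; unknown keys are rejected.
.default_run_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_per_class = 20L, class_set = c("normal", "GOLD2"),
                  breaths_per_subject = 3L),
    preprocess = list(rate = 200, filter_order = 3L, cutoff_hz = 10,
                      flow_threshold = 0.02, min_len = 16L, min_rise = 1.0,
                      paa_length = 224L),
    encode = list(kind = "GASF"),
    augment = list(enabled = TRUE, noise_mean = 0, noise_variance = 15,
                   alpha = 200, sigma = 20, alpha_affine = 10),
    model = list(n_classes = 2L, dropout = 0.4),
    train = list(lr = 0.001, batch = 32L, epochs = 30L, folds = 10L)
  )
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) document whose keys mirror the pipeline parameters;
#' missing keys take their defaults, unknown keys are rejected.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for pure defaults.
#' @return A nested list of resolved parameters.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_block <- function(def, got, where) {
    unknown <- setdiff(names(got), names(def))
    if (length(unknown)) stopf("unknown config key%s under %s: %s",
                               if (length(unknown) > 1) "s" else "", where,
                               paste(unknown, collapse = ", "))
    for (k in names(got)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(got[[k]])) {
        merge_block(def[[k]], got[[k]], paste0(where, "$", k))
      } else {
        got[[k]]
      }
    }
    def
  }
  merge_block(cfg, user, "config")
}

#' Write a resolved run configuration
#'
#' @param cfg A config list (see [read_run_config()]).
#' @param path Output path; written as YAML.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
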