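# Gramian Angular Field encoding: min-max normalization to [-1, 1], polar
# encoding via arccos, the summation (GASF) and difference (GADF) fields,
# and 8-bit grayscale quantization.
#
# For a normalized series x~ with angles phi_i = arccos(x~_i), the fields
# are GASF[i,j] = cos(phi_i + phi_j) and GADF[i,j] = sin(phi_i - phi_j).
# Equivalently, with s = sin(phi) = sqrt(1 - x~^2) (non-negative because
# phi lies in [0, pi]): GASF = x~ x~' - s s' and GADF = s x~' - x~ s'.

#' Min-max normalization to \[-1, 1\]
#'
#' `x~_i = 2 (x_i - min X) / (max X - min X) - 1`. A constant series is a
#' degenerate breath (the scaling denominator vanishes) and is rejected.
#'
#' @param x Numeric vector (typically a `paa_series`).
#' @return A `normalized_series` in \[-1, 1\] whose min is -1 and max is 1.
#' @export
normalize_minmax <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x))) {
    stopf("normalization needs >= 2 finite samples")
  }
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stopf("constant series cannot be normalized (max == min)")
  structure(2 * (x - lo) / (hi - lo) - 1, class = "normalized_series")
}

#' Polar encoding of a normalized series
#'
#' Each sample becomes an angle `phi_i = arccos(x~_i)` in \[0, pi\]; the
#' radius `r_i = t_i / N` (with `t_i = i` for 1-based sample index `i` and
#' `N` the series length) records the time stamp and keeps the encoding
#' temporally consistent, but does not enter the field matrices.
#'
#' @param x A `normalized_series` (values in \[-1, 1\]).
#' @return A `polar_series`: list with `phi` and `r`.
#' @export
to_polar <- function(x) {
  x <- as.numeric(x)
  if (any(abs(x) > 1 + 1e-12)) {
    stopf("values outside [-1, 1] (max |x| = %.15g) cannot be angle-encoded",
          max(abs(x)))
  }
  x <- clip(x, -1, 1)
  n <- length(x)
  structure(list(phi = acos(x), r = seq_len(n) / n, n = n),
            class = "polar_series")
}

#' Gramian angular summation field
#'
#' `GASF[i, j] = cos(phi_i + phi_j)`; symmetric, with diagonal
#' `2 x~_i^2 - 1`.
#'
#' @param polar A `polar_series`.
#' @return A `gaf_matrix` with attribute `kind = "GASF"`, entries in
#'   \[-1, 1\].
#' @export
gasf_matrix <- function(polar) {
  stopifnot(inherits(polar, "polar_series"))
  x <- cos(polar$phi)
  s <- sin(polar$phi)
  m <- outer(x, x) - outer(s, s)
  structure(clip(m, -1, 1), class = "gaf_matrix", kind = "GASF")
}

#' Gramian angular difference field
#'
#' `GADF[i, j] = sin(phi_i - phi_j)`; antisymmetric with a zero diagonal.
#'
#' @param polar A `polar_series`.
#' @return A `gaf_matrix` with attribute `kind = "GADF"`.
#' @export
gadf_matrix <- function(polar) {
  stopifnot(inherits(polar, "polar_series"))
  x <- cos(polar$phi)
  s <- sin(polar$phi)
  m <- outer(s, x) - outer(x, s)
  structure(clip(m, -1, 1), class = "gaf_matrix", kind = "GADF")
}

# IEC 60559 round-half-to-even on the [-1,1] -> [0,255] linear map.
.quantize_unit <- function(m) {
  matrix(as.integer(round((m + 1) / 2 * 255)), nrow(m))
}

#' Encode a series as a GAF grayscale image
#'
#' Composition normalize -> polar -> GASF/GADF -> linear quantization of
#' \[-1, 1\] onto \[0, 255\] with round-half-to-even. A 224-sample series
#' yields a 224 x 224 image.
#'
#' @param x Numeric series (a `paa_series`); must be non-constant.
#' @param kind `"GASF"` or `"GADF"`.
#' @return A [gray_image()] of side `length(x)`.
#' @export
encode_image <- function(x, kind = c("GASF", "GADF")) {
  kind <- match.arg(kind)
  polar <- to_polar(normalize_minmax(x))
  m <- if (kind == "GASF") gasf_matrix(polar) else gadf_matrix(polar)
  gray_image(.quantize_unit(unclass(m)), kind = kind,
             subject_id = attr(x, "subject_id"), label = attr(x, "label"))
}
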