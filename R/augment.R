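# Training-set augmentation: additive Gaussian noise in 8-bit intensity
# units, and elastic deformation (smoothed random displacement field plus a
# small random affine perturbation), expanding the training set to exactly
# three times its size. Augmentation is meant for training folds only; the
# cross-validation harness never augments held-out data.

#' Gaussian noise parameters
#'
#' @param mean Noise mean in intensity levels; default 0.
#' @param variance Noise variance in intensity levels squared; default 15
#'   (standard deviation about 3.87 gray levels).
#' @return A `noise_params` list.
#' @export
noise_params <- function(mean = 0, variance = 15) {
  check_number(variance, "variance", lower = 0)
  structure(list(mean = mean, variance = variance), class = "noise_params")
}

#' Elastic deformation parameters
#'
#' @param alpha Displacement intensity (pixels) scaling the smoothed random
#'   field; default 200.
#' @param sigma Width (pixels) of the Gaussian kernel smoothing the
#'   displacement field (its elasticity); default 20.
#' @param alpha_affine Bound (pixels) of the uniform perturbation applied to
#'   the three affine anchor corners; default 10.
#' @return An `elastic_params` list.
#' @export
elastic_params <- function(alpha = 200, sigma = 20, alpha_affine = 10) {
  check_number(alpha, "alpha", lower = 0)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(alpha_affine, "alpha_affine", lower = 0)
  structure(list(alpha = alpha, sigma = sigma, alpha_affine = alpha_affine),
            class = "elastic_params")
}

#' Add i.i.d. Gaussian noise to a grayscale image
#'
#' `pixel' = clip(round(pixel + e), 0, 255)` with
#' `e ~ Normal(mean, variance)` drawn independently per pixel.
#'
#' @param img A [gray_image()].
#' @param params A [noise_params()].
#' @param seed Integer seed; identical inputs and seed give an identical
#'   output.
#' @return A `gray_image` of the same size and kind.
#' @export
add_gaussian_noise <- function(img, params = noise_params(), seed = 1L) {
  stopifnot(inherits(img, "gray_image"), inherits(params, "noise_params"))
  if (params$variance == 0 && params$mean == 0) return(img)
  e <- with_seed(seed, stats::rnorm(length(img), params$mean,
                                    sqrt(params$variance)))
  px <- clip(round(unclass(img) + e), 0, 255)
  gray_image(px, kind = attr(img, "kind"),
             subject_id = attr(img, "subject_id"), label = attr(img, "label"))
}

# Mirror coordinate x into [1, n] (reflection border without edge
# duplication); identity on in-range coordinates.
.reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  r <- abs(x - 1) %% p
  1 + pmin(r, p - r)
}

# n x n Gaussian smoothing operator with reflection border handling;
# applied as K %*% U %*% t(K) this smooths rows and columns.
.gauss_smoother <- function(n, sigma) {
  rad <- min(max(1L, ceiling(3 * sigma)), 4L * n)
  offs <- -rad:rad
  g <- exp(-offs^2 / (2 * sigma^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(offs)) {
    j <- round(.reflect_coord(i + offs[k], n))
    K[cbind(i, j)] <- K[cbind(i, j)] + g[k]
  }
  K
}

# Bilinear sample of matrix img at (real-valued) row coords sy, col coords
# sx, both already reflected into [1, n].
.bilinear <- function(img, sy, sx) {
  n <- nrow(img)
  y0 <- pmin(floor(sy), n - 1); y1 <- y0 + 1
  x0 <- pmin(floor(sx), n - 1); x1 <- x0 + 1
  wy <- sy - y0; wx <- sx - x0
  v00 <- img[cbind(y0, x0)]; v01 <- img[cbind(y0, x1)]
  v10 <- img[cbind(y1, x0)]; v11 <- img[cbind(y1, x1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Elastic deformation of a grayscale image
#'
#' Draws per-pixel displacement fields `u ~ Uniform(-1, 1)`, smooths each
#' with a Gaussian kernel of width `sigma` and scales by `alpha`
#' (`dx = alpha * G_sigma(u)`); composes this with a random affine map
#' obtained by perturbing three anchor corners of the image by
#' `Uniform(-alpha_affine, alpha_affine)` pixels; resamples with bilinear
#' interpolation and reflection border handling. With `alpha = 0` and
#' `alpha_affine = 0` the output equals the input.
#'
#' @param img A [gray_image()].
#' @param params An [elastic_params()].
#' @param seed Integer seed.
#' @return A deformed `gray_image` of the same size and kind.
#' @export
elastic_transform <- function(img, params = elastic_params(), seed = 1L) {
  stopifnot(inherits(img, "gray_image"), inherits(params, "elastic_params"))
  n <- nrow(img)
  px <- unclass(img)
  draws <- with_seed(seed, list(
    ux = matrix(stats::runif(n * n, -1, 1), n),
    uy = matrix(stats::runif(n * n, -1, 1), n),
    corner_jit = stats::runif(6, -params$alpha_affine, params$alpha_affine)
  ))
  # output pixel grid (row = y, col = x)
  ygrid <- matrix(seq_len(n), n, n)
  xgrid <- matrix(seq_len(n), n, n, byrow = TRUE)
  sy <- ygrid
  sx <- xgrid
  if (params$alpha_affine > 0) {
    # anchor corners (x, y): top-left, top-right, bottom-left
    src <- rbind(c(1, 1), c(n, 1), c(1, n))
    dst <- src + matrix(draws$corner_jit, 3, 2)
    # affine A taking src -> dst; sample source coords via its inverse
    M <- cbind(src, 1)
    coef <- solve(M, dst)          # 3x2: [a; b; c] per output coordinate
    A <- rbind(cbind(t(coef[1:2, , drop = FALSE]), coef[3, ]), c(0, 0, 1))
    Ainv <- solve(A)
    sx <- Ainv[1, 1] * xgrid + Ainv[1, 2] * ygrid + Ainv[1, 3]
    sy <- Ainv[2, 1] * xgrid + Ainv[2, 2] * ygrid + Ainv[2, 3]
  }
  if (params$alpha > 0) {
    K <- .gauss_smoother(n, params$sigma)
    sx <- sx + params$alpha * (K %*% draws$ux %*% t(K))
    sy <- sy + params$alpha * (K %*% draws$uy %*% t(K))
  }
  sx <- .reflect_coord(sx, n)
  sy <- .reflect_coord(sy, n)
  out <- matrix(.bilinear(px, as.vector(sy), as.vector(sx)), n)
  gray_image(clip(round(out), 0, 255), kind = attr(img, "kind"),
             subject_id = attr(img, "subject_id"), label = attr(img, "label"))
}

#' Expand a training set threefold
#'
#' Returns the original images, one Gaussian-noise copy of each, and one
#' elastically deformed copy of each, in that order: exactly `3 N` images
#' for `N` inputs. Metadata (subject, label, kind) is carried over;
#' augmented copies record their source position in attribute
#' `source_index`.
#'
#' @param images Non-empty list of [gray_image()]s.
#' @param seed Integer seed.
#' @param noise A [noise_params()].
#' @param elastic An [elastic_params()].
#' @return A list of `3 * length(images)` gray images.
#' @export
expand_training_set <- function(images, seed = 1L, noise = noise_params(),
                                elastic = elastic_params()) {
  if (!length(images)) stopf("cannot augment an empty training set")
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max, 2L * length(images)))
  originals <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    attr(img, "source_index") <- i
    attr(img, "augmented") <- "none"
    img
  })
  noised <- lapply(seq_along(images), function(i) {
    img <- add_gaussian_noise(images[[i]], noise, seed = seeds[i])
    attr(img, "source_index") <- i
    attr(img, "augmented") <- "noise"
    img
  })
  deformed <- lapply(seq_along(images), function(i) {
    img <- elastic_transform(images[[i]], elastic,
                             seed = seeds[length(images) + i])
    attr(img, "source_index") <- i
    attr(img, "augmented") <- "elastic"
    img
  })
  c(originals, noised, deformed)
}
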