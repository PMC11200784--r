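# CapnoNet: a compact multi-scale CNN for GAF-encoded capnograms.
#
# Pinned architecture (for a 1 x 224 x 224 input):
#   conv 3x3, 1 -> 32 (no bias) + BN + ReLU          at 224 x 224
#   max pool 2x2 / stride 2, three times             224 -> 112 -> 56 -> 28
#   inception module 1: four parallel branches 32 -> 26 with kernels
#     1/3/5/7 (each conv + BN + ReLU), concatenated -> 104 channels at 28 x 28
#   max pool twice                                   28 -> 14 -> 7
#   inception module 2: 104 -> 108 x 4 branches -> 432 channels at 7 x 7
#   global average pooling -> 432-vector
#   dropout 0.4
#   fully connected 432 -> n_classes, softmax at inference
#
# Convolutions are bias-free (each is followed by BN); all convolutions are
# stride-1 "same"; all downsampling is pooling. This configuration has
# 1,015,666 trainable parameters with a binary head and costs 230,949,312
# FLOPs per forward pass at 224 x 224 (counting 2 x the conv/FC
# multiply-accumulates).

#' CapnoNet model configuration
#'
#' @param n_classes Number of output classes (>= 2); 2 for COPD detection,
#'   4 (GOLD 1-4) or 5 (adding normal) for severity grading.
#' @param in_side Input image side (pixels); default 224. The parameter
#'   count does not depend on it; FLOPs scale with its square.
#' @param stem_channels Channels of the initial 3x3 convolution; default 32.
#' @param branch_widths Per-branch output channels of the two inception
#'   modules; default `c(26, 108)`.
#' @param kernel_sizes Kernel sizes of the four parallel inception branches;
#'   pinned to `c(1, 3, 5, 7)`.
#' @param dropout Dropout rate applied between global average pooling and
#'   the fully connected layer; default 0.4.
#' @return A `capnonet_config` list.
#' @export
capnonet_config <- function(n_classes = 2L, in_side = 224L,
                            stem_channels = 32L, branch_widths = c(26L, 108L),
                            kernel_sizes = c(1L, 3L, 5L, 7L), dropout = 0.4) {
  check_number(n_classes, "n_classes", lower = 2)
  check_number(in_side, "in_side", lower = 8)
  check_number(dropout, "dropout", lower = 0, upper = 1, strict_upper = TRUE)
  if (!identical(sort(as.integer(kernel_sizes)), c(1L, 3L, 5L, 7L))) {
    stopf("kernel_sizes must be exactly {1, 3, 5, 7}")
  }
  if (length(branch_widths) != 2L || any(branch_widths < 1)) {
    stopf("branch_widths must be two positive channel counts")
  }
  structure(list(n_classes = as.integer(n_classes),
                 in_side = as.integer(in_side),
                 stem_channels = as.integer(stem_channels),
                 branch_widths = as.integer(branch_widths),
                 kernel_sizes = as.integer(sort(kernel_sizes)),
                 dropout = dropout),
            class = "capnonet_config")
}

# Layer plan: types convblock / pool / inception / gap / dropout / fc.
.capnonet_arch <- function(cfg) {
  w1 <- cfg$branch_widths[1]
  w2 <- cfg$branch_widths[2]
  c1 <- 4L * w1
  list(
    list(type = "convblock", name = "stem", cin = 1L,
         cout = cfg$stem_channels, k = 3L),
    list(type = "pool"), list(type = "pool"), list(type = "pool"),
    list(type = "inception", name = "inc1", cin = cfg$stem_channels,
         width = w1, kernels = cfg$kernel_sizes),
    list(type = "pool"), list(type = "pool"),
    list(type = "inception", name = "inc2", cin = c1, width = w2,
         kernels = cfg$kernel_sizes),
    list(type = "gap"),
    list(type = "dropout", p = cfg$dropout),
    list(type = "fc", name = "fc", cin = 4L * w2, cout = cfg$n_classes)
  )
}

.init_conv <- function(cout, cin, k) {
  matrix(stats::rnorm(cout * k * k * cin, 0, sqrt(2 / (k * k * cin))),
         cout, k * k * cin)
}

#' Build a CapnoNet model
#'
#' Instantiates the pinned architecture with He-initialized, bias-free
#' convolution weights, unit-gamma/zero-beta batch normalization and a
#' zero-bias fully connected head. Spatial sizes are checked at build time
#' (224 pools to 28 before inception 1 and to 7 before inception 2).
#'
#' @param cfg A [capnonet_config()].
#' @param seed Integer seed for weight initialization; the same seed gives
#'   identical initial weights.
#' @return A `capnonet` object (untrained).
#' @export
build_capnonet <- function(cfg = capnonet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "capnonet_config"))
  arch <- .capnonet_arch(cfg)
  params <- list()
  state <- list()
  with_seed(seed, {
    for (ly in arch) {
      if (ly$type == "convblock") {
        params[[paste0(ly$name, ".W")]] <- .init_conv(ly$cout, ly$cin, ly$k)
        params[[paste0(ly$name, ".gamma")]] <- rep(1, ly$cout)
        params[[paste0(ly$name, ".beta")]] <- rep(0, ly$cout)
        state[[paste0(ly$name, ".rm")]] <- rep(0, ly$cout)
        state[[paste0(ly$name, ".rv")]] <- rep(1, ly$cout)
      } else if (ly$type == "inception") {
        for (k in ly$kernels) {
          nm <- sprintf("%s.k%d", ly$name, k)
          params[[paste0(nm, ".W")]] <- .init_conv(ly$width, ly$cin, k)
          params[[paste0(nm, ".gamma")]] <- rep(1, ly$width)
          params[[paste0(nm, ".beta")]] <- rep(0, ly$width)
          state[[paste0(nm, ".rm")]] <- rep(0, ly$width)
          state[[paste0(nm, ".rv")]] <- rep(1, ly$width)
        }
      } else if (ly$type == "fc") {
        params[[paste0(ly$name, ".W")]] <-
          matrix(stats::rnorm(ly$cout * ly$cin, 0, sqrt(1 / ly$cin)),
                 ly$cout, ly$cin)
        params[[paste0(ly$name, ".b")]] <- rep(0, ly$cout)
      }
    }
  })
  model <- structure(list(cfg = cfg, arch = arch, params = params,
                          state = state, trained = FALSE, history = NULL),
                     class = "capnonet")
  # spatial-size audit for the reference geometry
  sides <- .trace_sides(model, cfg$in_side)
  if (cfg$in_side == 224L &&
      !(sides$inception[1] == 28L && sides$inception[2] == 7L)) {
    stopf("pooling schedule broken: inception modules at %d and %d, expected 28 and 7",
          sides$inception[1], sides$inception[2])
  }
  model
}

# Sides at which each inception module operates, plus the final side.
.trace_sides <- function(model, side) {
  inception <- integer(0)
  for (ly in model$arch) {
    if (ly$type == "pool") side <- side %/% 2L
    if (ly$type == "inception") inception <- c(inception, side)
  }
  list(inception = inception, final = side)
}

# Forward pass. x: 1 x (side^2 * B) matrix of pixel intensities in [0, 1].
# Returns logits (n_classes x B); with cache = TRUE also per-layer caches
# for the backward pass; training = TRUE uses batch BN statistics and
# active dropout (drawing from the current RNG stream) and returns updated
# running statistics.
.capnonet_forward <- function(model, x, side, B, training = FALSE,
                              cache = FALSE) {
  P <- model$params
  S <- model$state
  H <- side
  W <- side
  caches <- list()
  for (li in seq_along(model$arch)) {
    ly <- model$arch[[li]]
    if (ly$type == "convblock") {
      cv <- .conv_fwd(x, H, W, B, P[[paste0(ly$name, ".W")]], ly$k)
      bn <- .bn_fwd(cv$y, P[[paste0(ly$name, ".gamma")]],
                    P[[paste0(ly$name, ".beta")]],
                    S[[paste0(ly$name, ".rm")]], S[[paste0(ly$name, ".rv")]],
                    training)
      if (training) {
        S[[paste0(ly$name, ".rm")]] <- bn$rm
        S[[paste0(ly$name, ".rv")]] <- bn$rv
      }
      y <- bn$y
      mask <- y > 0
      x <- y * mask
      if (cache) caches[[li]] <- list(cols = cv$cols, xhat = bn$xhat,
                                      ivar = bn$ivar, mask = mask,
                                      H = H, W = W)
    } else if (ly$type == "pool") {
      pl <- .pool_fwd(x, H, W, B)
      if (cache) caches[[li]] <- list(arg = pl$arg, H = H, W = W)
      x <- pl$y
      H <- pl$Ho
      W <- pl$Wo
    } else if (ly$type == "inception") {
      outs <- vector("list", length(ly$kernels))
      cc <- list(H = H, W = W, branches = list())
      for (bi in seq_along(ly$kernels)) {
        k <- ly$kernels[bi]
        nm <- sprintf("%s.k%d", ly$name, k)
        cv <- .conv_fwd(x, H, W, B, P[[paste0(nm, ".W")]], k)
        bn <- .bn_fwd(cv$y, P[[paste0(nm, ".gamma")]], P[[paste0(nm, ".beta")]],
                      S[[paste0(nm, ".rm")]], S[[paste0(nm, ".rv")]], training)
        if (training) {
          S[[paste0(nm, ".rm")]] <- bn$rm
          S[[paste0(nm, ".rv")]] <- bn$rv
        }
        y <- bn$y
        mask <- y > 0
        outs[[bi]] <- y * mask
        if (cache) cc$branches[[bi]] <- list(cols = cv$cols, xhat = bn$xhat,
                                             ivar = bn$ivar, mask = mask)
      }
      if (cache) {
        cc$cin <- ly$cin
        caches[[li]] <- cc
      }
      x <- do.call(rbind, outs)
    } else if (ly$type == "gap") {
      if (cache) caches[[li]] <- list(HW = H * W)
      x <- .gap_fwd(x, H * W, B)
      H <- 1L
      W <- 1L
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        mask <- matrix(stats::runif(length(x)) >= ly$p, nrow(x)) / (1 - ly$p)
        x <- x * mask
        if (cache) caches[[li]] <- list(mask = mask)
      } else if (cache) {
        caches[[li]] <- list(mask = NULL)
      }
    } else if (ly$type == "fc") {
      if (cache) caches[[li]] <- list(xin = x)
      x <- P[[paste0(ly$name, ".W")]] %*% x + P[[paste0(ly$name, ".b")]]
    }
  }
  list(logits = x, caches = caches, state = S, B = B)
}

# Backward pass mirroring .capnonet_forward; returns gradients named like
# model$params.
.capnonet_backward <- function(model, dlogits, caches, side, B) {
  P <- model$params
  grads <- list()
  d <- dlogits
  H <- side
  W <- side
  for (li in rev(seq_along(model$arch))) {
    ly <- model$arch[[li]]
    cc <- caches[[li]]
    if (ly$type == "fc") {
      grads[[paste0(ly$name, ".W")]] <- tcrossprod(d, cc$xin)
      grads[[paste0(ly$name, ".b")]] <- rowSums(d)
      d <- crossprod(P[[paste0(ly$name, ".W")]], d)
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) d <- d * cc$mask
    } else if (ly$type == "gap") {
      d <- .gap_bwd(d, cc$HW, B)
    } else if (ly$type == "inception") {
      dx <- NULL
      row0 <- 0L
      for (bi in seq_along(ly$kernels)) {
        k <- ly$kernels[bi]
        nm <- sprintf("%s.k%d", ly$name, k)
        br <- cc$branches[[bi]]
        wdt <- nrow(br$xhat)
        db <- d[(row0 + 1L):(row0 + wdt), , drop = FALSE] * br$mask
        row0 <- row0 + wdt
        bn <- .bn_bwd(db, br, P[[paste0(nm, ".gamma")]])
        grads[[paste0(nm, ".gamma")]] <- bn$dgamma
        grads[[paste0(nm, ".beta")]] <- bn$dbeta
        cvb <- .conv_bwd(bn$dx, br, cc$H, cc$W, B, P[[paste0(nm, ".W")]],
                         k, ly$cin)
        grads[[paste0(nm, ".W")]] <- cvb$dW
        dx <- if (is.null(dx)) cvb$dx else dx + cvb$dx
      }
      d <- dx
    } else if (ly$type == "pool") {
      d <- .pool_bwd(d, cc, cc$H, cc$W, B)
    } else if (ly$type == "convblock") {
      d <- d * cc$mask
      bn <- .bn_bwd(d, cc, P[[paste0(ly$name, ".gamma")]])
      grads[[paste0(ly$name, ".gamma")]] <- bn$dgamma
      grads[[paste0(ly$name, ".beta")]] <- bn$dbeta
      cvb <- .conv_bwd(bn$dx, cc, cc$H, cc$W, B, P[[paste0(ly$name, ".W")]],
                       ly$k, ly$cin)
      grads[[paste0(ly$name, ".W")]] <- cvb$dW
      d <- cvb$dx
    }
  }
  grads
}

# Stack a list of gray images into the 1 x (side^2 * B) input matrix,
# intensities scaled to [0, 1].
.images_to_input <- function(images) {
  side <- nrow(images[[1]])
  x <- vapply(images, function(im) as.numeric(im) / 255,
              numeric(side * side))
  list(x = matrix(as.vector(x), nrow = 1L), side = side, B = length(images))
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: bias-free convolution weights, batch-norm
#' affine pairs, and the fully connected weights and bias. The count does
#' not depend on the input side. The pinned binary configuration has
#' 1,015,666 parameters (1.02 M).
#'
#' @param model A `capnonet` model.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "capnonet"))
  sum(vapply(model$params, length, integer(1)))
}

#' Count forward-pass FLOPs
#'
#' FLOPs are twice the multiply-accumulates of all convolutions and the
#' fully connected layer; a convolution with kernel `k`, `Cin` inputs and
#' `Cout` outputs at spatial size `H x W` contributes `k^2 Cin Cout H W`
#' MACs. Batch norm, activations and pooling are excluded. The pinned
#' binary configuration costs 230,949,312 FLOPs (0.23 GFLOPs) at 224 x 224.
#'
#' @param model A `capnonet` model.
#' @param in_side Input side the count is taken at; default 224.
#' @return FLOP count (numeric).
#' @export
count_flops <- function(model, in_side = 224L) {
  stopifnot(inherits(model, "capnonet"))
  side <- as.integer(in_side)
  macs <- 0
  for (ly in model$arch) {
    if (ly$type == "convblock") {
      macs <- macs + as.numeric(ly$k)^2 * ly$cin * ly$cout * side^2
    } else if (ly$type == "pool") {
      side <- side %/% 2L
    } else if (ly$type == "inception") {
      macs <- macs + sum(as.numeric(ly$kernels)^2) * ly$cin * ly$width * side^2
    } else if (ly$type == "fc") {
      macs <- macs + as.numeric(ly$cin) * ly$cout
    }
  }
  2 * macs
}

#' Classify grayscale images with a CapnoNet model
#'
#' Runs the network in inference mode (running batch-norm statistics,
#' dropout off), so repeated calls on the same input are identical.
#'
#' @param object A `capnonet` model.
#' @param images List of [gray_image()]s with side equal to the side the
#'   model was trained at (any side works for an untrained model).
#' @param type `"prob"` for the softmax matrix (images x classes) or
#'   `"class"` for the arg-max class index.
#' @param batch Mini-batch size used during inference.
#' @param ... Unused.
#' @return A probability matrix or an integer vector of class indices.
#' @export
predict.capnonet <- function(object, images, type = c("prob", "class"),
                             batch = 32L, ...) {
  type <- match.arg(type)
  if (!length(images)) stopf("no images to classify")
  n <- length(images)
  probs <- matrix(0, n, object$cfg$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    inp <- .images_to_input(images[i:j])
    out <- .capnonet_forward(object, inp$x, inp$side, inp$B,
                             training = FALSE)
    probs[i:j, ] <- t(.softmax(out$logits))
    i <- j + 1L
  }
  if (!is.null(object$class_levels)) colnames(probs) <- object$class_levels
  if (type == "prob") probs else max.col(probs, ties.method = "first")
}

#' @export
print.capnonet <- function(x, ...) {
  cat(sprintf("CapnoNet (%d classes, input %dx%d)\n",
              x$cfg$n_classes, x$cfg$in_side, x$cfg$in_side))
  cat(sprintf("  parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  cat(sprintf("  forward FLOPs at 224x224: %s (%.2f GFLOPs)\n",
              format(count_flops(x), big.mark = ","),
              count_flops(x) / 1e9))
  cat(sprintf("  trained: %s\n", if (isTRUE(x$trained)) "yes" else "no"))
  invisible(x)
}

#' @export
summary.capnonet <- function(object, ...) {
  print(object)
  side <- object$cfg$in_side
  cat("  layers:\n")
  for (ly in object$arch) {
    desc <- switch(ly$type,
      convblock = sprintf("conv %dx%d %d->%d + BN + ReLU @ %dx%d",
                          ly$k, ly$k, ly$cin, ly$cout, side, side),
      pool = {
        side <- side %/% 2L
        sprintf("maxpool 2x2/s2 -> %dx%d", side, side)
      },
      inception = sprintf("inception %d->4x%d (k=1/3/5/7) -> %d @ %dx%d",
                          ly$cin, ly$width, 4L * ly$width, side, side),
      gap = "global average pool",
      dropout = sprintf("dropout p=%.1f", ly$p),
      fc = sprintf("fc %d -> %d", ly$cin, ly$cout))
    cat("   -", desc, "\n")
    if (ly$type == "pool") next
  }
  invisible(object)
}
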