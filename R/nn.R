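# Minimal CNN engine on BLAS matrix products.
#
# A feature map batch is stored as a C x (H*W*B) matrix: image b occupies
# columns ((b-1)*H*W + 1):(b*H*W), pixels ordered column-major over (h, w).
# Convolutions are im2col + GEMM; all convolutions are stride-1 with
# zero-padding preserving the spatial size ("same"); downsampling happens
# only in 2x2/stride-2 max pooling. Every layer has an explicit backward
# pass; optimization is Adam on softmax cross-entropy.

# Cache of index vectors for im2col / pooling, keyed by geometry.
.idx_cache <- new.env(parent = emptyenv())

.conv_indices <- function(H, W, B, k) {
  key <- sprintf("conv_%d_%d_%d_%d", H, W, B, k)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  p <- (k - 1L) %/% 2L
  P <- H + 2L * p
  Q <- W + 2L * p
  # linear index of inner pixel (h, w) inside the padded P x Q plane
  inner <- as.vector(outer(seq_len(H) + p, seq_len(W) + p - 1L,
                           function(h, wm) (wm) * P + h))
  inner_all <- rep(inner, B) + rep((seq_len(B) - 1L) * P * Q, each = H * W)
  # base linear index of output pixel (i, j) in the padded plane
  base <- as.vector(outer(seq_len(H), seq_len(W) - 1L,
                          function(i, jm) jm * P + i))
  offs <- vector("list", k * k)
  o <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      o <- o + 1L
      idx <- base + (kj - 1L) * P + (ki - 1L)
      offs[[o]] <- rep(idx, B) + rep((seq_len(B) - 1L) * P * Q, each = H * W)
    }
  }
  res <- list(p = p, P = P, Q = Q, inner_all = inner_all, offs = offs)
  .idx_cache[[key]] <- res
  res
}

.im2col <- function(x, H, W, B, k) {
  C <- nrow(x)
  if (k == 1L) return(x)
  ix <- .conv_indices(H, W, B, k)
  xpad <- matrix(0, C, ix$P * ix$Q * B)
  xpad[, ix$inner_all] <- x
  cols <- matrix(0, k * k * C, H * W * B)
  for (o in seq_len(k * k)) {
    cols[((o - 1L) * C + 1L):(o * C), ] <- xpad[, ix$offs[[o]]]
  }
  cols
}

.col2im <- function(dcols, C, H, W, B, k) {
  if (k == 1L) return(dcols)
  ix <- .conv_indices(H, W, B, k)
  dpad <- matrix(0, C, ix$P * ix$Q * B)
  for (o in seq_len(k * k)) {
    idx <- ix$offs[[o]]
    dpad[, idx] <- dpad[, idx] + dcols[((o - 1L) * C + 1L):(o * C), ]
  }
  dpad[, ix$inner_all]
}

.conv_fwd <- function(x, H, W, B, Wmat, k) {
  cols <- .im2col(x, H, W, B, k)
  list(y = Wmat %*% cols, cols = cols)
}

.conv_bwd <- function(dY, cache, H, W, B, Wmat, k, cin) {
  dW <- tcrossprod(dY, cache$cols)
  dcols <- crossprod(Wmat, dY)
  list(dW = dW, dx = .col2im(dcols, cin, H, W, B, k))
}

.bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                    eps = 1e-5) {
  if (training) {
    N <- ncol(x)
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * ivar
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * v * N / max(N - 1, 1)
    list(y = xhat * gamma + beta, xhat = xhat, ivar = ivar,
         rm = rm_new, rv = rv_new)
  } else {
    ivar <- 1 / sqrt(rv + eps)
    list(y = (x - rm) * ivar * gamma + beta)
  }
}

.bn_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dx <- (gamma * cache$ivar) *
    (dY - rowMeans(dY) - xhat * rowMeans(dY * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.pool_indices <- function(H, W, B) {
  key <- sprintf("pool_%d_%d_%d", H, W, B)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  io <- seq_len(Ho)
  jo <- seq_len(Wo)
  lin <- function(di, dj) {
    as.vector(outer(2L * io - 2L + di, 2L * jo - 2L + dj,
                    function(i, j) (j - 1L) * H + i))
  }
  q <- list(lin(1L, 1L), lin(2L, 1L), lin(1L, 2L), lin(2L, 2L))
  q <- lapply(q, function(v) {
    rep(v, B) + rep((seq_len(B) - 1L) * H * W, each = Ho * Wo)
  })
  res <- list(Ho = Ho, Wo = Wo, q = q)
  .idx_cache[[key]] <- res
  res
}

.pool_fwd <- function(x, H, W, B) {
  ix <- .pool_indices(H, W, B)
  y <- x[, ix$q[[1]], drop = FALSE]
  arg <- matrix(1L, nrow(y), ncol(y))
  for (k in 2:4) {
    m <- x[, ix$q[[k]], drop = FALSE]
    sel <- m > y
    y[sel] <- m[sel]
    arg[sel] <- k
  }
  list(y = y, arg = arg, Ho = ix$Ho, Wo = ix$Wo)
}

.pool_bwd <- function(dY, cache, H, W, B) {
  ix <- .pool_indices(H, W, B)
  dx <- matrix(0, nrow(dY), H * W * B)
  for (k in 1:4) {
    idx <- ix$q[[k]]
    dx[, idx] <- dx[, idx] + dY * (cache$arg == k)
  }
  dx
}

.gap_fwd <- function(x, HW, B) {
  C <- nrow(x)
  y <- matrix(0, C, B)
  for (b in seq_len(B)) {
    y[, b] <- rowMeans(x[, ((b - 1L) * HW + 1L):(b * HW), drop = FALSE])
  }
  y
}

.gap_bwd <- function(dY, HW, B) {
  C <- nrow(dY)
  dx <- matrix(0, C, HW * B)
  for (b in seq_len(B)) {
    dx[, ((b - 1L) * HW + 1L):(b * HW)] <- dY[, b] / HW
  }
  dx
}

# Softmax cross-entropy over columns; labels are 1-based class indices.
.softmax_ce <- function(logits, labels) {
  z <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                       byrow = TRUE)
  ez <- exp(z)
  p <- ez / matrix(colSums(ez), nrow(z), ncol(z), byrow = TRUE)
  B <- ncol(p)
  picked <- p[cbind(labels, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(B))] <-
    dlogits[cbind(labels, seq_len(B))] - 1
  list(loss = loss, p = p, dlogits = dlogits / B)
}

.softmax <- function(logits) {
  z <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                       byrow = TRUE)
  ez <- exp(z)
  ez / matrix(colSums(ez), nrow(z), ncol(z), byrow = TRUE)
}

# One Adam step; st holds first/second moments and the step counter.
.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / b1t) / (sqrt(st$v[[nm]] / b2t) + eps)
  }
  list(params = params, st = st)
}

.adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}
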