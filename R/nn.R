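# Minimal neural-network engine: dense and 3x3 same-padding convolution layers,
# 2x2 average pooling, nearest-neighbour upsampling, ReLU, softmax, and Adam.
# Written in-package because the adversarial training scheme needs exact control
# over which parameter partition each loss updates; feature maps are stored as
# arrays with dim (H, W, C, n) and dense activations as (n x d) matrices.

# ---- initialisation ---------------------------------------------------------

nn_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

# Conv weights stored as a (k*k*C_in) x C_out matrix; row order: kernel offset
# fastest, then input channel (must match nn_im2col's column order).
nn_conv <- function(c_in, c_out, k = 3) {
  fan_in <- k * k * c_in
  list(W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = numeric(c_out), k = k)
}

# ---- im2col indices (cached per spatial shape) ------------------------------

.nn_cache <- new.env(parent = emptyenv())

conv_index <- function(H, W, k = 3) {
  key <- paste(H, W, k, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  pad <- (k - 1L) / 2L
  Hp <- H + 2L * pad
  P <- H * W
  ind <- matrix(0L, P, k * k)
  pos <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    # output (i, j), 1-based; padded source (i + di, j + dj) in 1..Hp/Wp
    i <- rep.int(seq_len(H), W) + di
    j <- rep(seq_len(W), each = H) + dj
    ind[, pos] <- (j - 1L) * Hp + i
    pos <- pos + 1L
  }
  .nn_cache[[key]] <- ind
  ind
}

# ---- convolution ------------------------------------------------------------

# x: (H, W, C, n) -> M: (P*n) x (k*k*C); rows: position fastest, then sample.
nn_im2col <- function(x, k = 3) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  pad <- (k - 1L) / 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xpad <- array(0, c(Hp, Wp, C, n))
  xpad[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , ] <- x
  xpf <- matrix(xpad, Hp * Wp, C * n)
  ind <- conv_index(H, W, k)
  M0 <- xpf[as.vector(ind), , drop = FALSE]        # (P*K) x (C*n)
  P <- H * W; K <- k * k
  M <- aperm(array(M0, c(P, K, C, n)), c(1, 4, 2, 3))
  dim(M) <- c(P * n, K * C)
  M
}

conv_forward <- function(x, layer) {
  d <- dim(x); H <- d[1]; W <- d[2]; n <- d[4]
  M <- nn_im2col(x, layer$k)
  Y <- M %*% layer$W
  Y <- Y + matrix(layer$b, nrow(Y), ncol(Y), byrow = TRUE)
  co <- ncol(layer$W)
  y <- aperm(array(Y, c(H, W, n, co)), c(1, 2, 4, 3))
  list(y = y, M = M, in_dim = d)
}

conv_backward <- function(dy, fwd, layer) {
  d <- fwd$in_dim; H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  k <- layer$k; K <- k * k; P <- H * W
  co <- dim(dy)[3]
  dYm <- aperm(dy, c(1, 2, 4, 3))
  dim(dYm) <- c(P * n, co)
  dW <- crossprod(fwd$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(layer$W)                          # (P*n) x (K*C)
  dM <- aperm(array(dM, c(P, n, K, C)), c(1, 3, 4, 2))
  dim(dM) <- c(P * K, C * n)
  ind <- as.vector(conv_index(H, W, k))
  pad <- (k - 1L) / 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  acc <- rowsum(dM, group = ind)                    # sorted unique indices
  dxpad <- matrix(0, Hp * Wp, C * n)
  dxpad[as.integer(rownames(acc)), ] <- acc
  dxpad <- array(dxpad, c(Hp, Wp, C, n))
  dx <- dxpad[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# 1x1 convolution as a channel-wise dense map; x: (H, W, C, n).
conv1x1_forward <- function(x, layer) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  Y <- xm %*% layer$W
  Y <- Y + matrix(layer$b, nrow(Y), ncol(Y), byrow = TRUE)
  y <- aperm(array(Y, c(d[1], d[2], d[4], ncol(layer$W))), c(1, 2, 4, 3))
  list(y = y, xm = xm, in_dim = d)
}

conv1x1_backward <- function(dy, fwd, layer) {
  d <- fwd$in_dim
  co <- dim(dy)[3]
  dYm <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], co)
  dW <- crossprod(fwd$xm, dYm)
  db <- colSums(dYm)
  dxm <- dYm %*% t(layer$W)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dW = dW, db = db, dx = dx)
}

# ---- pooling / upsampling ---------------------------------------------------

avgpool2 <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  x6 <- array(x, c(2L, H2, 2L, W2, d[3], d[4]))
  (x6[1, , 1, , , , drop = FALSE] + x6[2, , 1, , , , drop = FALSE] +
     x6[1, , 2, , , , drop = FALSE] + x6[2, , 2, , , , drop = FALSE]) / 4 ->
    y
  array(y, c(H2, W2, d[3], d[4]))
}

avgpool2_backward <- function(dy, in_dim) {
  H2 <- in_dim[1] %/% 2L; W2 <- in_dim[2] %/% 2L
  g <- array(dy / 4, c(1L, H2, 1L, W2, in_dim[3], in_dim[4]))
  dx6 <- array(0, c(2L, H2, 2L, W2, in_dim[3], in_dim[4]))
  for (i in 1:2) for (j in 1:2) dx6[i, , j, , , ] <- g
  array(dx6, in_dim)
}

upsample2 <- function(x) {
  d <- dim(x)
  y6 <- array(0, c(2L, d[1], 2L, d[2], d[3], d[4]))
  xr <- array(x, c(1L, d[1], 1L, d[2], d[3], d[4]))
  for (i in 1:2) for (j in 1:2) y6[i, , j, , , ] <- xr
  array(y6, c(2L * d[1], 2L * d[2], d[3], d[4]))
}

upsample2_backward <- function(dy) {
  d <- dim(dy); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  y6 <- array(dy, c(2L, H2, 2L, W2, d[3], d[4]))
  out <- y6[1, , 1, , , , drop = FALSE] + y6[2, , 1, , , , drop = FALSE] +
    y6[1, , 2, , , , drop = FALSE] + y6[2, , 2, , , , drop = FALSE]
  array(out, c(H2, W2, d[3], d[4]))
}

# ---- dense / activations ----------------------------------------------------

dense_forward <- function(x, layer) {
  y <- x %*% layer$W
  y + matrix(layer$b, nrow(y), ncol(y), byrow = TRUE)
}

dense_backward <- function(dy, x, layer) {
  list(dW = crossprod(x, dy), db = colSums(dy), dx = dy %*% t(layer$W))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dy, y) dy * (y > 0)

# Parameter-free batch normalisation over the sample dimension of an
# (n x F) matrix. Keeping every Qrepr feature at unit variance prevents the
# extractor from hiding domain information in low-variance directions that
# the online domain classifier cannot see but a converged post-hoc probe
# (which standardises its inputs) would recover; it also conditions the
# adversarial game. Running statistics are used at inference time.
batchnorm_forward <- function(x, stats, training = TRUE,
                              momentum = 0.1, eps = 1e-5) {
  if (training && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
  }
  sigma <- sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  list(y = xhat, xhat = xhat, sigma = sigma, stats = stats,
       batch_stats = training && nrow(x) > 1)
}

batchnorm_backward <- function(dy, cache) {
  if (!cache$batch_stats)          # fixed statistics: pure rescaling
    return(sweep(dy, 2, cache$sigma, "/"))
  n <- nrow(dy)
  xhat <- cache$xhat
  m1 <- colMeans(dy)
  m2 <- colMeans(dy * xhat)
  sweep(dy - rep(1, n) %o% m1 - xhat * (rep(1, n) %o% m2),
        2, cache$sigma, "/")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

# params/grads: nested named lists whose leaves are numeric arrays named W/b.
# `path` keys the per-leaf moment estimates inside the state environment.
adam_update <- function(params, grads, state, lr = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8, path = "") {
  for (nm in names(grads)) {
    p <- params[[nm]]; g <- grads[[nm]]
    key <- paste0(path, "/", nm)
    if (is.list(p)) {
      params[[nm]] <- adam_update(p, g, state, lr, beta1, beta2, eps, key)
    } else if (is.numeric(p)) {
      st <- state[[key]]
      if (is.null(st)) st <- list(m = 0 * p, v = 0 * p, t = 0L)
      st$t <- st$t + 1L
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^st$t)
      vhat <- st$v / (1 - beta2^st$t)
      params[[nm]] <- p - lr * mhat / (sqrt(vhat) + eps)
      state[[key]] <- st
    }
  }
  params
}
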