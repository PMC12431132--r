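# Minimal feed-forward network engine: 2D/1D convolution ('same' padding),
# max pooling, dropout, flatten, dense layers, sigmoid/binary cross-entropy
# head, Adam optimiser. Convolutions are evaluated as im2col matrix
# products so the heavy lifting is BLAS matrix multiplication. Batches are
# 4D arrays (H, W, C, B) for images and 3D arrays (L, C, B) for sequences.

nn_relu <- function(x) pmax(x, 0)
nn_sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(fan_in, n) {
  limit <- sqrt(6 / fan_in)
  runif(n, -limit, limit)
}

# ---- layer constructors (shapes resolved at build time) --------------------

nn_conv2d <- function(in_shape, filters, kernel = c(3, 3),
                      activation = "relu") {
  k <- prod(kernel) * in_shape[3]
  list(type = "conv2d",
       W = matrix(he_init(k, k * filters), k, filters),
       b = numeric(filters),
       kernel = kernel, activation = activation,
       in_shape = in_shape, out_shape = c(in_shape[1:2], filters))
}

nn_maxpool2d <- function(in_shape, size = 2) {
  out <- c(floor(in_shape[1] / size), floor(in_shape[2] / size), in_shape[3])
  if (any(out[1:2] < 1))
    stop("pooling would collapse a ", in_shape[1], "x", in_shape[2],
         " feature map to zero size")
  list(type = "maxpool2d", size = size, in_shape = in_shape, out_shape = out)
}

nn_conv1d <- function(in_shape, filters, kernel,
                      activation = "relu") {
  if (in_shape[1] < kernel)
    stop("input length ", in_shape[1], " shorter than kernel ", kernel)
  k <- kernel * in_shape[2]
  list(type = "conv1d",
       W = matrix(he_init(k, k * filters), k, filters),
       b = numeric(filters),
       kernel = kernel, activation = activation,
       in_shape = in_shape, out_shape = c(in_shape[1], filters))
}

nn_maxpool1d <- function(in_shape, size) {
  out <- c(floor(in_shape[1] / size), in_shape[2])
  if (out[1] < 1) stop("pooling would collapse the sequence to zero length")
  list(type = "maxpool1d", size = size, in_shape = in_shape, out_shape = out)
}

nn_dropout <- function(in_shape, rate) {
  list(type = "dropout", rate = rate, in_shape = in_shape,
       out_shape = in_shape)
}

nn_flatten <- function(in_shape) {
  list(type = "flatten", in_shape = in_shape, out_shape = prod(in_shape))
}

nn_dense <- function(in_dim, units, activation = "linear") {
  list(type = "dense",
       W = matrix(he_init(in_dim, in_dim * units), in_dim, units),
       b = numeric(units),
       activation = activation, in_shape = in_dim, out_shape = units)
}

nn_param_count <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

# ---- im2col helpers --------------------------------------------------------

im2col2d <- function(Xp, H, W, C, B, kh, kw) {
  cols <- matrix(0, H * W * B, kh * kw * C)
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    j <- j + 1L
    cols[, j] <- Xp[dy:(dy + H - 1), dx:(dx + W - 1), c, ]
  }
  cols
}

col2im2d <- function(dcols, dimXp, H, W, C, B, kh, kw) {
  dXp <- array(0, dimXp)
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    j <- j + 1L
    dXp[dy:(dy + H - 1), dx:(dx + W - 1), c, ] <-
      dXp[dy:(dy + H - 1), dx:(dx + W - 1), c, ] + dcols[, j]
  }
  dXp
}

# ---- forward/backward per layer -------------------------------------------

layer_forward <- function(layer, X, training = FALSE) {
  switch(layer$type,
    conv2d = {
      d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
      kh <- layer$kernel[1]; kw <- layer$kernel[2]
      ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
      Xp <- array(0, c(H + kh - 1, W + kw - 1, C, B))
      Xp[(ph + 1):(ph + H), (pw + 1):(pw + W), , ] <- X
      cols <- im2col2d(Xp, H, W, C, B, kh, kw)
      Ym <- sweep(cols %*% layer$W, 2, layer$b, "+")
      F <- ncol(layer$W)
      Y <- aperm(array(Ym, c(H, W, B, F)), c(1, 2, 4, 3))
      if (layer$activation == "relu") Y <- nn_relu(Y)
      list(out = Y, cache = list(cols = cols, mask = (Y > 0),
                                 dimXp = dim(Xp), dims = d))
    },
    conv1d = {
      d <- dim(X); L <- d[1]; C <- d[2]; B <- d[3]
      k <- layer$kernel
      pl <- (k - 1) %/% 2
      Xp <- array(0, c(L + k - 1, C, B))
      Xp[(pl + 1):(pl + L), , ] <- X
      cols <- matrix(0, L * B, k * C)
      j <- 0L
      for (c in seq_len(C)) for (dk in seq_len(k)) {
        j <- j + 1L
        cols[, j] <- Xp[dk:(dk + L - 1), c, ]
      }
      Ym <- sweep(cols %*% layer$W, 2, layer$b, "+")
      F <- ncol(layer$W)
      Y <- aperm(array(Ym, c(L, B, F)), c(1, 3, 2))
      if (layer$activation == "relu") Y <- nn_relu(Y)
      list(out = Y, cache = list(cols = cols, mask = (Y > 0),
                                 dimXp = dim(Xp), dims = d))
    },
    maxpool2d = {
      d <- dim(X); s <- layer$size
      Hf <- d[1] %/% s; Wf <- d[2] %/% s
      idx_i <- lapply(seq_len(s), function(o) seq(o, s * Hf, s))
      idx_j <- lapply(seq_len(s), function(o) seq(o, s * Wf, s))
      Y <- NULL
      parts <- list()
      for (oi in seq_len(s)) for (oj in seq_len(s)) {
        P <- X[idx_i[[oi]], idx_j[[oj]], , , drop = FALSE]
        parts[[length(parts) + 1L]] <- P
        Y <- if (is.null(Y)) P else pmax(Y, P)
      }
      list(out = Y, cache = list(parts = parts, Y = Y, dims = d,
                                 idx_i = idx_i, idx_j = idx_j))
    },
    maxpool1d = {
      d <- dim(X); s <- layer$size
      Lf <- d[1] %/% s
      idx <- lapply(seq_len(s), function(o) seq(o, s * Lf, s))
      Y <- NULL
      parts <- list()
      for (o in seq_len(s)) {
        P <- X[idx[[o]], , , drop = FALSE]
        parts[[o]] <- P
        Y <- if (is.null(Y)) P else pmax(Y, P)
      }
      list(out = Y, cache = list(parts = parts, Y = Y, dims = d, idx = idx))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (runif(length(X)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(X)
        list(out = X * mask, cache = list(mask = mask))
      } else {
        list(out = X, cache = list(mask = NULL))
      }
    },
    flatten = {
      d <- dim(X); B <- d[length(d)]
      list(out = t(matrix(X, ncol = B)), cache = list(dims = d))
    },
    dense = {
      Y <- sweep(X %*% layer$W, 2, layer$b, "+")
      if (layer$activation == "relu") Y <- nn_relu(Y)
      list(out = Y, cache = list(X = X, mask = (Y > 0)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dOut, cache) {
  switch(layer$type,
    conv2d = {
      d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
      kh <- layer$kernel[1]; kw <- layer$kernel[2]
      ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
      if (layer$activation == "relu") dOut <- dOut * cache$mask
      dZm <- matrix(aperm(dOut, c(1, 2, 4, 3)), ncol = ncol(layer$W))
      dW <- crossprod(cache$cols, dZm)
      db <- colSums(dZm)
      dcols <- tcrossprod(dZm, layer$W)
      dXp <- col2im2d(dcols, cache$dimXp, H, W, C, B, kh, kw)
      dX <- dXp[(ph + 1):(ph + H), (pw + 1):(pw + W), , , drop = FALSE]
      list(dX = dX, dW = dW, db = db)
    },
    conv1d = {
      d <- cache$dims; L <- d[1]; C <- d[2]; B <- d[3]
      k <- layer$kernel; pl <- (k - 1) %/% 2
      if (layer$activation == "relu") dOut <- dOut * cache$mask
      dZm <- matrix(aperm(dOut, c(1, 3, 2)), ncol = ncol(layer$W))
      dW <- crossprod(cache$cols, dZm)
      db <- colSums(dZm)
      dcols <- tcrossprod(dZm, layer$W)
      dXp <- array(0, cache$dimXp)
      j <- 0L
      for (c in seq_len(C)) for (dk in seq_len(k)) {
        j <- j + 1L
        dXp[dk:(dk + L - 1), c, ] <- dXp[dk:(dk + L - 1), c, ] + dcols[, j]
      }
      list(dX = dXp[(pl + 1):(pl + L), , , drop = FALSE], dW = dW, db = db)
    },
    maxpool2d = {
      d <- cache$dims; s <- layer$size
      dX <- array(0, d)
      taken <- array(FALSE, dim(cache$Y))
      p <- 0L
      for (oi in seq_len(s)) for (oj in seq_len(s)) {
        p <- p + 1L
        m <- (cache$parts[[p]] == cache$Y) & !taken
        taken <- taken | m
        dX[cache$idx_i[[oi]], cache$idx_j[[oj]], , ] <- dOut * m
      }
      list(dX = dX)
    },
    maxpool1d = {
      d <- cache$dims; s <- layer$size
      dX <- array(0, d)
      taken <- array(FALSE, dim(cache$Y))
      for (o in seq_len(s)) {
        m <- (cache$parts[[o]] == cache$Y) & !taken
        taken <- taken | m
        dX[cache$idx[[o]], , ] <- dOut * m
      }
      list(dX = dX)
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dOut)
      else list(dX = dOut * cache$mask)
    },
    flatten = {
      list(dX = array(t(dOut), cache$dims))
    },
    dense = {
      if (layer$activation == "relu") dOut <- dOut * cache$mask
      list(dX = tcrossprod(dOut, layer$W),
           dW = crossprod(cache$X, dOut),
           db = colSums(dOut))
    }
  )
}

# Forward pass through the whole network. Returns the head logits and, when
# `keep` is given, the output of that layer index as well.
nn_forward <- function(net, X, training = FALSE, keep = NULL) {
  caches <- if (training) vector("list", length(net$layers)) else NULL
  kept <- NULL
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], X, training = training)
    X <- r$out
    if (training) caches[[i]] <- r$cache
    if (!is.null(keep) && i == keep) kept <- X
  }
  list(logits = X, caches = caches, kept = kept)
}

nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    g <- layer_backward(net$layers[[i]], dOut, caches[[i]])
    dOut <- g$dX
    grads[[i]] <- g
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (is.null(l$W)) NULL
    else list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    if (is.null(state[[i]])) next
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mWh <- s$mW / (1 - beta1^t); vWh <- s$vW / (1 - beta2^t)
    mbh <- s$mb / (1 - beta1^t); vbh <- s$vb / (1 - beta2^t)
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * mWh / (sqrt(vWh) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * mbh / (sqrt(vbh) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

bce_loss <- function(logits, y) {
  p <- nn_sigmoid(logits)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
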