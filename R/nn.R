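# Minimal neural-network engine: 1-D convolution (via the compiled
# im2col kernels), batch normalization, ReLU, ceil max-pooling, dropout,
# dense layers, Adam, binary cross-entropy. Tensors are R arrays laid out
# (channels, length, batch); dense activations are (features, batch)
# matrices. All randomness (init, shuffling, dropout) draws from R's RNG,
# so training is deterministic for a fixed seed.

nn_dense <- function(n_in, n_out) {
  sd <- sqrt(2 / n_in)  # He initialization
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(stats::rnorm(n_out * n_in, 0, sd), n_out),
                     b = numeric(n_out)))
}

nn_conv <- function(c_in, c_out, k) {
  sd <- sqrt(2 / (c_in * k))
  list(type = "conv", c_in = c_in, c_out = c_out, k = as.integer(k),
       params = list(W = matrix(stats::rnorm(c_out * c_in * k, 0, sd), c_out),
                     b = numeric(c_out)))
}

nn_bn <- function(c) {
  list(type = "bn", c = c, eps = 1e-5, momentum = 0.9,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       run_mean = numeric(c), run_var = rep(1, c))
}

nn_relu <- function() list(type = "relu", params = list())
nn_pool <- function() list(type = "pool", params = list())
nn_dropout <- function(rate) list(type = "dropout", rate = rate,
                                  params = list())
nn_flatten <- function() list(type = "flatten", params = list())

# Channel-wise matrix view of a (C, L, B) array: C is the first dim, so a
# plain dim-drop gives (C, L*B) without copying semantics changing.
as_cmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

layer_fwd <- function(layer, x, train) {
  switch(layer$type,
    dense = {
      out <- layer$params$W %*% x + layer$params$b
      list(out = out, cache = x, layer = layer)
    },
    conv = {
      out <- .conv1d_fw(x, layer$params$W, layer$params$b, layer$k)
      list(out = out, cache = x, layer = layer)
    },
    bn = {
      d <- dim(x)
      xm <- as_cmat(x)
      M <- d[2] * d[3]
      if (train) {
        mu <- .rowMeans(xm, d[1], M)
        v <- .rowMeans(xm^2, d[1], M) - mu^2
        layer$run_mean <- layer$momentum * layer$run_mean +
          (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var +
          (1 - layer$momentum) * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      ivar <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - mu) * ivar
      out <- layer$params$gamma * xhat + layer$params$beta
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, ivar = ivar, d = d),
           layer = layer)
    },
    relu = {
      out <- x
      out[out < 0] <- 0
      list(out = out, cache = (x > 0), layer = layer)
    },
    pool = {
      d <- dim(x)
      L <- d[2]
      if (L == 1) return(list(out = x, cache = NULL, layer = layer))
      Lp <- ceiling(L / 2)
      xp <- array(-Inf, c(d[1], 2 * Lp, d[3]))
      xp[, seq_len(L), ] <- x
      a <- xp[, seq(1, 2 * Lp, 2), , drop = FALSE]
      b <- xp[, seq(2, 2 * Lp, 2), , drop = FALSE]
      left <- a >= b
      out <- pmax(a, b)
      list(out = out, cache = list(left = left, L = L), layer = layer)
    },
    dropout = {
      if (!train || layer$rate == 0)
        return(list(out = x, cache = NULL, layer = layer))
      keep <- 1 - layer$rate
      mask <- array(stats::runif(length(x)) < keep, dim(x)) / keep
      list(out = x * mask, cache = mask, layer = layer)
    },
    flatten = {
      d <- dim(x)
      dim(x) <- c(d[1] * d[2], d[3])
      list(out = x, cache = d, layer = layer)
    },
    stop("unknown layer type ", layer$type))
}

layer_bwd <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    dense = {
      list(dx = if (need_dx) crossprod(layer$params$W, dout),
           grads = list(W = tcrossprod(dout, cache), b = rowSums(dout)))
    },
    conv = {
      r <- .conv1d_bw(cache, layer$params$W, dout, layer$k, need_dx)
      list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    bn = {
      d <- cache$d
      M <- d[2] * d[3]
      dm <- dout
      dim(dm) <- c(d[1], M)
      dgamma <- .rowSums(dm * cache$xhat, d[1], M)
      dbeta <- .rowSums(dm, d[1], M)
      dxhat <- layer$params$gamma * dm
      dx <- cache$ivar / M *
        (M * dxhat - .rowSums(dxhat, d[1], M) -
           cache$xhat * .rowSums(dxhat * cache$xhat, d[1], M))
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache, grads = list()),
    pool = {
      if (is.null(cache)) return(list(dx = dout, grads = list()))
      d <- dim(dout)
      dxp <- array(0, c(d[1], 2 * d[2], d[3]))
      dxp[, seq(1, 2 * d[2], 2), ] <- dout * cache$left
      dxp[, seq(2, 2 * d[2], 2), ] <- dout * !cache$left
      list(dx = dxp[, seq_len(cache$L), , drop = FALSE], grads = list())
    },
    dropout = {
      if (is.null(cache)) return(list(dx = dout, grads = list()))
      list(dx = dout * cache, grads = list())
    },
    flatten = {
      dim(dout) <- cache
      list(dx = dout, grads = list())
    })
}

chain_fwd <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

chain_bwd <- function(layers, caches, dout, need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], dout,
                   need_dx = need_input_grad || i > 1)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(chains) {
  lapply(chains, function(layers)
    lapply(layers, function(l)
      lapply(l$params, function(p) list(m = p * 0, v = p * 0))))
}

adam_step <- function(chains, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (cn in names(chains)) {
    for (i in seq_along(chains[[cn]])) {
      g <- grads[[cn]][[i]]
      if (!length(g)) next
      for (pn in names(g)) {
        st <- state[[cn]][[i]][[pn]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[pn]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[pn]]^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        chains[[cn]][[i]]$params[[pn]] <-
          chains[[cn]][[i]]$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
        state[[cn]][[i]][[pn]] <- st
      }
    }
  }
  list(chains = chains, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
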