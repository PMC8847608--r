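# Minimal dense/conv/recurrent network engine with manual backpropagation.
# Tensors are column-major R arrays laid out (D, H, W, C, N): temporal depth,
# height, width, channels, batch. Convolutions are stride-1 "same"; pooling
# windows are non-overlapping with floor division. Heavy kernels (im2col GEMM
# convolution, max pooling) live in src/nn_ops.cpp.

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_conv3d <- function(in_ch, out_ch, kdim = c(3L, 3L, 3L)) {
  K <- prod(kdim) * in_ch
  list(type = "conv3d", kdim = as.integer(kdim), in_ch = in_ch,
       out_ch = out_ch,
       W = matrix(stats::rnorm(K * out_ch, 0, sqrt(2 / K)), K, out_ch),
       b = numeric(out_ch))
}

layer_pool3d <- function(pool) list(type = "pool3d", pool = as.integer(pool))
layer_relu <- function() list(type = "relu")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")
layer_time_flatten <- function() list(type = "time_flatten")
layer_last_step <- function() list(type = "last_step")

layer_dense <- function(n_in, n_out, final = FALSE) {
  sd <- if (final) sqrt(1 / n_in) else sqrt(2 / n_in)
  list(type = "dense", W = matrix(stats::rnorm(n_in * n_out, 0, sd),
                                  n_out, n_in),
       b = numeric(n_out))
}

layer_lstm <- function(n_in, n_hidden) {
  H <- n_hidden
  sc <- sqrt(1 / max(n_in, H))
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1 # forget-gate bias
  list(type = "lstm", n_hidden = H,
       Wx = matrix(stats::runif(4 * H * n_in, -sc, sc), 4 * H, n_in),
       Wh = matrix(stats::runif(4 * H * H, -sc, sc), 4 * H, H),
       b = b)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv3d = {
      y <- cpp_conv3d_fw(x, dim(x), layer$W, layer$b, layer$kdim)
      list(y = y, cache = list(x = x, xdim = dim(x)))
    },
    pool3d = {
      r <- cpp_maxpool3d_fw(x, dim(x), layer$pool)
      list(y = r$y, cache = list(idx = r$idx, xlen = length(x),
                                 xdim = dim(x)))
    },
    relu = {
      y <- cpp_relu_fw(x)
      list(y = y, cache = list(y = y))
    },
    dropout = {
      if (!training || layer$rate == 0) return(list(y = x, cache = NULL))
      keep <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
      y <- x * keep
      if (!is.null(dim(x))) dim(y) <- dim(x)
      list(y = y, cache = list(keep = keep))
    },
    flatten = {
      d <- dim(x)
      n <- d[length(d)]
      list(y = matrix(x, ncol = n), cache = list(xdim = d))
    },
    time_flatten = {
      # (D,H,W,C,N) -> (H*W*C, D, N): per-frame feature vectors
      d <- dim(x)
      y <- aperm(x, c(2L, 3L, 4L, 1L, 5L))
      dim(y) <- c(d[2] * d[3] * d[4], d[1], d[5])
      list(y = y, cache = list(xdim = d))
    },
    last_step = {
      d <- dim(x)
      list(y = matrix(x[, d[2], ], d[1], d[3]), cache = list(xdim = d))
    },
    dense = {
      y <- layer$W %*% x + layer$b
      list(y = y, cache = list(x = x))
    },
    lstm = lstm_forward(layer, x),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv3d = {
      r <- cpp_conv3d_bw(cache$x, cache$xdim, layer$W, dy, layer$kdim,
                         need_dx)
      list(dx = r$dx, grads = list(W = r$dw, b = as.numeric(r$db)))
    },
    pool3d = {
      dx <- cpp_maxpool3d_bw(cache$idx, dy, cache$xlen)
      dim(dx) <- cache$xdim
      list(dx = dx, grads = NULL)
    },
    relu = list(dx = cpp_relu_bw(cache$y, dy), grads = NULL),
    dropout = {
      if (is.null(cache)) return(list(dx = dy, grads = NULL))
      dx <- dy * cache$keep
      if (!is.null(dim(dy))) dim(dx) <- dim(dy)
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dim(dy) <- cache$xdim
      list(dx = dy, grads = NULL)
    },
    time_flatten = {
      d <- cache$xdim
      dim(dy) <- c(d[2], d[3], d[4], d[1], d[5])
      list(dx = aperm(dy, c(4L, 1L, 2L, 3L, 5L)), grads = NULL)
    },
    last_step = {
      d <- cache$xdim
      dx <- array(0, d)
      dx[, d[2], ] <- dy
      list(dx = dx, grads = NULL)
    },
    dense = list(dx = crossprod(layer$W, dy),
                 grads = list(W = tcrossprod(dy, cache$x),
                              b = rowSums(dy))),
    lstm = lstm_backward(layer, cache, dy),
    stop("unknown layer type: ", layer$type))
}

lstm_forward <- function(layer, x) {
  d <- dim(x) # (F, D, N)
  Fi <- d[1]; D <- d[2]; N <- d[3]
  H <- layer$n_hidden
  h <- matrix(0, H, N)
  cc <- matrix(0, H, N)
  y <- array(0, c(H, D, N))
  steps <- vector("list", D)
  ih <- 1:H; fh <- (H + 1):(2 * H); gh <- (2 * H + 1):(3 * H)
  oh <- (3 * H + 1):(4 * H)
  for (t in seq_len(D)) {
    xt <- matrix(x[, t, ], Fi, N)
    z <- layer$Wx %*% xt + layer$Wh %*% h + layer$b
    i <- sigmoid(z[ih, , drop = FALSE])
    f <- sigmoid(z[fh, , drop = FALSE])
    g <- tanh(z[gh, , drop = FALSE])
    o <- sigmoid(z[oh, , drop = FALSE])
    steps[[t]] <- list(xt = xt, hprev = h, cprev = cc, i = i, f = f,
                       g = g, o = o)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    steps[[t]]$tc <- tanh(cc)
    y[, t, ] <- h
  }
  list(y = y, cache = list(steps = steps, xdim = d))
}

lstm_backward <- function(layer, cache, dy) {
  d <- cache$xdim
  Fi <- d[1]; D <- d[2]; N <- d[3]
  H <- layer$n_hidden
  dWx <- matrix(0, 4 * H, Fi)
  dWh <- matrix(0, 4 * H, H)
  db <- numeric(4 * H)
  dx <- array(0, d)
  dh_next <- matrix(0, H, N)
  dc_next <- matrix(0, H, N)
  for (t in rev(seq_len(D))) {
    s <- cache$steps[[t]]
    dh <- matrix(dy[, t, ], H, N) + dh_next
    do <- dh * s$tc
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$cprev
    dc_next <- dc * s$f
    dz <- rbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dWx <- dWx + tcrossprod(dz, s$xt)
    dWh <- dWh + tcrossprod(dz, s$hprev)
    db <- db + rowSums(dz)
    dx[, t, ] <- crossprod(layer$Wx, dz)
    dh_next <- crossprod(layer$Wh, dz)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$y
    caches[i] <- list(r$cache) # keep NULL entries (stateless layers)
  }
  list(out = x, caches = caches)
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], dout,
                        need_dx = i > 1L) # input gradient is never consumed
    dout <- r$dx
    grads[i] <- list(r$grads) # keep NULL entries (no-parameter layers)
  }
  grads
}

# logits: (3 x N); y_onehot: (3 x N). Returns loss and dlogits.
softmax_xent <- function(logits, y_onehot) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(logits)
  loss <- -sum(y_onehot * log(pmax(p, 1e-12))) / n
  list(loss = loss, probs = p, dlogits = (p - y_onehot) / n)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

PARAM_NAMES <- c("W", "b", "Wx", "Wh")

# AMSGrad: adaptive moment estimation with a non-decreasing second-moment
# cap. Bias-corrected first/second moments, per the common implementation.
amsgrad_init <- function(model) {
  lapply(model$layers, function(l) {
    ps <- intersect(PARAM_NAMES, names(l))
    if (!length(ps)) return(NULL)
    st <- lapply(ps, function(p) {
      z <- l[[p]] * 0
      list(m = z, v = z, vhat = z)
    })
    names(st) <- ps
    st
  })
}

amsgrad_step <- function(model, grads, state, lr, step,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      s <- state[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g[[p]]
      s$v <- beta2 * s$v + (1 - beta2) * g[[p]]^2
      mhat <- s$m / (1 - beta1^step)
      vhat <- s$v / (1 - beta2^step)
      s$vhat <- pmax(s$vhat, vhat)
      upd <- lr * mhat / (sqrt(s$vhat) + eps)
      dim(upd) <- dim(s$m)
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] - upd
      state[[i]][[p]] <- s
    }
  }
  list(model = model, state = state)
}
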