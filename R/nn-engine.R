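# Minimal neural-network engine on base-R BLAS.
#
# Activations flow through the convolutional stack as 3D arrays of shape
# (channels, length, batch) and through dense heads as matrices of shape
# (features, batch). Every layer implements a forward pass (returning output,
# a cache for backprop, and the possibly updated layer state — batch norm
# running statistics) and a backward pass (returning the input gradient and
# parameter gradients shaped exactly like the parameters). All heavy lifting
# is matrix multiplication so the engine runs at BLAS speed; everything is
# double precision and deterministic given the R RNG state and a fixed BLAS
# thread count.

# ---- layer constructors -----------------------------------------------------

layer_avgpool <- function(window) {
  list(type = "avgpool", window = as.integer(window), params = list())
}

layer_conv1d <- function(in_ch, out_ch, filter_size = 5L, dilation = 2L) {
  if (filter_size %% 2L != 1L) stop_validation("filter_size must be odd")
  if (dilation < 1L) stop_validation("dilation must be >= 1")
  # He initialisation: fan-in = in_ch * filter_size
  w <- array(stats::rnorm(out_ch * in_ch * filter_size,
                          sd = sqrt(2 / (in_ch * filter_size))),
             dim = c(out_ch, in_ch, filter_size))
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch,
       filter_size = as.integer(filter_size), dilation = as.integer(dilation),
       params = list(W = w, b = numeric(out_ch)))
}

layer_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", channels = channels, momentum = momentum, eps = eps,
       running_mean = numeric(channels), running_var = rep(1, channels),
       params = list(gamma = rep(1, channels), beta = numeric(channels)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(in_dim, out_dim) {
  w <- matrix(stats::rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)), out_dim, in_dim)
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = w, b = numeric(out_dim)))
}

layer_dropout <- function(p) {
  if (p < 0 || p >= 1) stop_validation("dropout probability must be in [0, 1)")
  list(type = "dropout", p = p, params = list())
}

layer_bilstm <- function(input_size, hidden_size) {
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nc)), nr, nc)
  dirp <- function() list(Wx = mk(4L * hidden_size, input_size),
                          Wh = mk(4L * hidden_size, hidden_size),
                          b = numeric(4L * hidden_size))
  list(type = "bilstm", input_size = input_size, hidden_size = hidden_size,
       params = list(fwd = dirp(), bwd = dirp()))
}

# Extracts the final bidirectional representation from an (2H, T, B) sequence:
# forward direction's state after the last step, backward direction's after
# its last step (input position 1).
layer_last_concat <- function(hidden_size) {
  list(type = "last_concat", hidden_size = hidden_size, params = list())
}

# ---- forward ----------------------------------------------------------------

forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$type,
    avgpool = {
      w <- layer$window
      d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
      pad <- (w - L %% w) %% w
      if (pad > 0L) {
        last <- x[, L, , drop = FALSE]
        x <- array(c(aperm(x, c(1, 3, 2)), rep(aperm(last, c(1, 3, 2)), pad)),
                   dim = c(C, B, L + pad))
        x <- aperm(x, c(1, 3, 2))
        L <- L + pad
      }
      lout <- L %/% w
      x4 <- x; dim(x4) <- c(C, w, lout, B)
      out <- colSums(aperm(x4, c(2, 1, 3, 4))) / w
      dim(out) <- c(C, lout, B)
      list(out = out, cache = list(dim_in = d, pad = pad), layer = layer)
    },
    conv1d = {
      d <- dim(x); C <- d[1L]
      w <- layer$params$W; dim(w) <- c(layer$out_ch, C * layer$filter_size)
      r <- cpp_conv1d_fwd(x, w, layer$params$b, layer$filter_size,
                          layer$dilation)
      list(out = r$out, cache = list(xc = r$xc, L = d[2L], B = d[3L]),
           layer = layer)
    },
    batchnorm = {
      d <- dim(x)
      m <- x; dim(m) <- c(d[1L], prod(d[-1L]))
      n <- ncol(m)
      if (training) {
        r <- cpp_bn_fwd(m, layer$params$gamma, layer$params$beta, layer$eps)
        out <- r$out
        xhat <- r$xhat
        invstd <- drop(r$invstd)
        unbiased <- if (n > 1L) drop(r$var) * n / (n - 1L) else drop(r$var)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * drop(r$mu)
        layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * unbiased
      } else {
        invstd <- 1 / sqrt(layer$running_var + layer$eps)
        xhat <- (m - layer$running_mean) * invstd
        out <- layer$params$gamma * xhat + layer$params$beta
      }
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, invstd = invstd, dim = d,
                                   training = training), layer = layer)
    },
    relu = {
      out <- cpp_relu_fwd(x)
      list(out = out, cache = list(out = out), layer = layer)
    },
    flatten = {
      d <- dim(x)
      out <- x; dim(out) <- c(prod(d[-length(d)]), d[length(d)])
      list(out = out, cache = list(dim_in = d), layer = layer)
    },
    dense = {
      out <- layer$params$W %*% x + layer$params$b
      list(out = out, cache = list(x = x), layer = layer)
    },
    dropout = {
      if (!training || layer$p == 0) {
        list(out = x, cache = list(mask = NULL), layer = layer)
      } else {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      }
    },
    bilstm = {
      fw <- lstm_dir_forward(layer$params$fwd, x, reverse = FALSE)
      bw <- lstm_dir_forward(layer$params$bwd, x, reverse = TRUE)
      d <- dim(x); Tt <- d[2L]; B <- d[3L]; H <- layer$hidden_size
      out <- array(0, dim = c(2L * H, Tt, B))
      out[seq_len(H), , ] <- fw$h_seq
      out[H + seq_len(H), , ] <- bw$h_seq
      list(out = out, cache = list(fw = fw, bw = bw, x = x), layer = layer)
    },
    last_concat = {
      d <- dim(x); H <- layer$hidden_size; Tt <- d[2L]
      out <- rbind(matrix(x[seq_len(H), Tt, ], H),
                   matrix(x[H + seq_len(H), 1L, ], H))
      list(out = out, cache = list(dim_in = d), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- backward ---------------------------------------------------------------

backward_layer <- function(layer, cache, dout) {
  switch(layer$type,
    avgpool = {
      w <- layer$window
      d <- cache$dim_in
      lout <- dim(dout)[2L]
      idx <- rep(seq_len(lout), each = w)
      dx <- dout[, idx, , drop = FALSE] / w
      if (cache$pad > 0L) {
        extra <- dx[, (d[2L] + 1L):(d[2L] + cache$pad), , drop = FALSE]
        dx <- dx[, seq_len(d[2L]), , drop = FALSE]
        dx[, d[2L], ] <- dx[, d[2L], ] + apply(extra, c(1, 3), sum)
      }
      list(dx = dx, grads = list())
    },
    conv1d = {
      C <- layer$in_ch
      w <- layer$params$W; dim(w) <- c(layer$out_ch, C * layer$filter_size)
      r <- cpp_conv1d_bwd(dout, cache$xc, w, C, layer$filter_size,
                          layer$dilation)
      dW <- r$dW; dim(dW) <- dim(layer$params$W)
      list(dx = r$dx, grads = list(W = dW, b = drop(r$db)))
    },
    batchnorm = {
      d <- cache$dim
      dm <- dout; dim(dm) <- c(d[1L], prod(d[-1L]))
      xhat <- cache$xhat
      if (cache$training) {
        r <- cpp_bn_bwd(dm, xhat, cache$invstd, layer$params$gamma)
        dx <- r$dx
        dgamma <- drop(r$dgamma); dbeta <- drop(r$dbeta)
      } else {
        dgamma <- rowSums(dm * xhat)
        dbeta <- rowSums(dm)
        dx <- cache$invstd * (layer$params$gamma * dm)
      }
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = cpp_relu_bwd(dout, cache$out), grads = list()),
    flatten = {
      dx <- dout; dim(dx) <- cache$dim_in
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = crossprod(layer$params$W, dout),
           grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    bilstm = {
      H <- layer$hidden_size
      dfw <- dout[seq_len(H), , , drop = FALSE]
      dbw <- dout[H + seq_len(H), , , drop = FALSE]
      bf <- lstm_dir_backward(layer$params$fwd, cache$fw, dfw, reverse = FALSE)
      bb <- lstm_dir_backward(layer$params$bwd, cache$bw, dbw, reverse = TRUE)
      list(dx = bf$dx + bb$dx, grads = list(fwd = bf$grads, bwd = bb$grads))
    },
    last_concat = {
      d <- cache$dim_in; H <- layer$hidden_size
      dx <- array(0, dim = d)
      dx[seq_len(H), d[2L], ] <- dout[seq_len(H), , drop = FALSE]
      dx[H + seq_len(H), 1L, ] <- dout[H + seq_len(H), , drop = FALSE]
      list(dx = dx, grads = list())
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- LSTM direction passes --------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_dir_forward <- function(p, x, reverse) {
  d <- dim(x); Tt <- d[2L]; B <- d[3L]
  H <- nrow(p$Wh) %/% 4L
  order_t <- if (reverse) rev(seq_len(Tt)) else seq_len(Tt)
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  h_seq <- array(0, dim = c(H, Tt, B))
  gates <- vector("list", Tt); cells <- vector("list", Tt)
  cprev <- vector("list", Tt)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  for (s in seq_len(Tt)) {
    t <- order_t[s]
    xt <- matrix(x[, t, ], d[1L], B)
    g <- p$Wx %*% xt + p$Wh %*% h + p$b
    gi <- sigmoid(g[ii, , drop = FALSE])
    gf <- sigmoid(g[ff, , drop = FALSE])
    gc <- tanh(g[gg, , drop = FALSE])
    go <- sigmoid(g[oo, , drop = FALSE])
    cprev[[s]] <- cc
    cc <- gf * cc + gi * gc
    tc <- tanh(cc)
    h <- go * tc
    h_seq[, t, ] <- h
    gates[[s]] <- list(i = gi, f = gf, g = gc, o = go, tc = tc, hprev_idx = s - 1L)
    cells[[s]] <- cc
  }
  list(h_seq = h_seq, gates = gates, cells = cells, cprev = cprev,
       order_t = order_t, x = x)
}

lstm_dir_backward <- function(p, cache, dh_seq, reverse) {
  x <- cache$x
  d <- dim(x); Tt <- d[2L]; B <- d[3L]
  H <- nrow(p$Wh) %/% 4L
  order_t <- cache$order_t
  dWx <- array(0, dim = dim(p$Wx)); dWh <- array(0, dim = dim(p$Wh))
  db <- numeric(4L * H)
  dx <- array(0, dim = d)
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  for (s in rev(seq_len(Tt))) {
    t <- order_t[s]
    g <- cache$gates[[s]]
    dh <- matrix(dh_seq[, t, ], H, B) + dh_next
    do_ <- dh * g$tc
    dc <- dc_next + dh * g$o * (1 - g$tc * g$tc)
    di <- dc * g$g
    dgc <- dc * g$i
    df <- dc * cache$cprev[[s]]
    dgates <- rbind(di * g$i * (1 - g$i),
                    df * g$f * (1 - g$f),
                    dgc * (1 - g$g * g$g),
                    do_ * g$o * (1 - g$o))
    xt <- matrix(x[, t, ], d[1L], B)
    hprev <- if (s == 1L) matrix(0, H, B) else matrix(cache$h_seq[, order_t[s - 1L], ], H, B)
    dWx <- dWx + dgates %*% t(xt)
    dWh <- dWh + dgates %*% t(hprev)
    db <- db + rowSums(dgates)
    dx[, t, ] <- dx[, t, , drop = FALSE] + array(crossprod(p$Wx, dgates), dim = c(d[1L], 1L, B))
    dh_next <- crossprod(p$Wh, dgates)
    dc_next <- dc * g$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- network-level passes ---------------------------------------------------

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- forward_layer(layers[[i]], x, training = training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- backward_layer(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    zero_like <- function(p) {
      if (is.list(p)) return(lapply(p, zero_like))
      if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
    }
    list(m = lapply(l$params, zero_like), v = lapply(l$params, zero_like))
  })
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    # bias correction folded into the step size; fused compiled update
    lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
    cpp_adam_step(p, m, v, g, lr_t, beta1, beta2, eps)
  }
  for (i in seq_along(layers)) {
    if (length(layers[[i]]$params) == 0L) next
    r <- upd(layers[[i]]$params, grads[[i]], state[[i]]$m, state[[i]]$v)
    layers[[i]]$params <- r$p
    state[[i]]$m <- r$m
    state[[i]]$v <- r$v
  }
  list(layers = layers, state = state)
}

# Count of learnable scalars in a layer stack.
nn_count_params <- function(layers) {
  cnt <- function(p) if (is.list(p)) sum(vapply(p, cnt, numeric(1))) else length(p)
  sum(vapply(layers, function(l) cnt(l$params), numeric(1)))
}
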