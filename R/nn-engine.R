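# Minimal neural-network engine: dense, 1-D (dilated, causal) convolution,
# gated residual convolution, LSTM, dropout, flatten; softmax cross-entropy
# loss and Adam. Activations are (n, T, C) arrays or (n, p) matrices; all
# heavy lifting is batched matrix multiplication so it runs on BLAS.
# Gradients of every layer are verified against finite differences in the
# test suite.

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer constructors ----------------------------------------------------

nn_conv1d <- function(in_ch, filters, kernel, dilation = 1L, causal = FALSE,
                      activation = c("relu", "linear")) {
  list(type = "conv1d", kernel = kernel, dilation = dilation, causal = causal,
       activation = match.arg(activation),
       par = list(W = glorot(c(kernel, in_ch, filters),
                             kernel * in_ch, kernel * filters),
                  b = numeric(filters)))
}

# one dilated causal convolution with gated activation tanh(u) * sigmoid(v)
# and a residual connection (1x1 projection when channel counts differ)
nn_gated_residual <- function(in_ch, filters, kernel, dilation) {
  par <- list(W = glorot(c(kernel, in_ch, 2L * filters),
                         kernel * in_ch, kernel * 2L * filters),
              b = numeric(2L * filters))
  if (in_ch != filters) {
    par$P <- glorot(c(in_ch, filters), in_ch, filters)
    par$pb <- numeric(filters)
  }
  list(type = "gated_residual", kernel = kernel, dilation = dilation,
       filters = filters, par = par)
}

nn_dense <- function(in_dim, out_dim, activation = c("relu", "linear")) {
  list(type = "dense", activation = match.arg(activation),
       par = list(W = glorot(c(in_dim, out_dim), in_dim, out_dim),
                  b = numeric(out_dim)))
}

nn_lstm <- function(in_ch, units) {
  b <- numeric(4L * units)
  b[(units + 1L):(2L * units)] <- 1  # forget-gate bias starts open
  list(type = "lstm", units = units,
       par = list(Wx = glorot(c(in_ch, 4L * units), in_ch, 4L * units),
                  Wh = glorot(c(units, 4L * units), units, 4L * units),
                  b = b))
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate, par = NULL)

nn_flatten <- function() list(type = "flatten", par = NULL)

# ---- convolution primitives ------------------------------------------------

pad_front <- function(x, pad) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + pad, d[3]))
  out[, (pad + 1L):(pad + d[2]), ] <- x
  out
}

conv1d_fwd <- function(x, W, b, dilation, relu = FALSE) {
  d <- dim(x); n <- d[1]; Tin <- d[2]; C <- d[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  Tout <- Tin - (k - 1L) * dilation
  z <- NULL
  for (j in seq_len(k)) {
    off <- (j - 1L) * dilation
    xj <- matrix(x[, (1L + off):(Tout + off), , drop = FALSE], n * Tout, C)
    zj <- xj %*% matrix(W[j, , ], C, f)
    z <- if (is.null(z)) zj else z + zj
  }
  cpp_bias_act_inplace(z, b, relu)  # z is a private temporary
  array(z, c(n, Tout, f))
}

conv1d_bwd <- function(x, W, dz) {
  d <- dim(x); n <- d[1]; Tin <- d[2]; C <- d[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  dilation <- attr(dz, "dilation")
  Tout <- dim(dz)[2]
  dz_mat <- matrix(dz, n * Tout, f)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (j in seq_len(k)) {
    off <- (j - 1L) * dilation
    idx <- (1L + off):(Tout + off)
    xj <- matrix(x[, idx, , drop = FALSE], n * Tout, C)
    dW[j, , ] <- crossprod(xj, dz_mat)
    dx[, idx, ] <- dx[, idx, , drop = FALSE] +
      array(dz_mat %*% t(matrix(W[j, , ], C, f)), c(n, Tout, C))
  }
  list(dx = dx, dW = dW, db = colSums(dz_mat))
}

# ---- forward / backward ----------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv1d = {
      xin <- if (layer$causal)
        pad_front(x, (layer$kernel - 1L) * layer$dilation) else x
      a <- conv1d_fwd(xin, layer$par$W, layer$par$b, layer$dilation,
                      relu = layer$activation == "relu")
      list(out = a, cache = list(xin = xin, a = a))
    },
    gated_residual = {
      f <- layer$filters
      xin <- pad_front(x, (layer$kernel - 1L) * layer$dilation)
      z <- conv1d_fwd(xin, layer$par$W, layer$par$b, layer$dilation)
      u <- z[, , seq_len(f), drop = FALSE]
      v <- z[, , f + seq_len(f), drop = FALSE]
      tu <- tanh(u); sv <- sigmoid(v)
      h <- tu * sv
      d <- dim(x)
      if (is.null(layer$par$P)) {
        res <- x
      } else {
        xm <- matrix(x, d[1] * d[2], d[3])
        res <- array(sweep(xm %*% layer$par$P, 2, layer$par$pb, "+"),
                     c(d[1], d[2], f))
      }
      list(out = h + res, cache = list(x = x, xin = xin, tu = tu, sv = sv))
    },
    dense = {
      z <- x %*% layer$par$W
      cpp_bias_act_inplace(z, layer$par$b, layer$activation == "relu")
      list(out = z, cache = list(x = x, a = z))
    },
    lstm = lstm_forward(layer, x),
    dropout = {
      if (!training || layer$rate <= 0)
        return(list(out = x, cache = NULL))
      dr <- cpp_dropout_fwd(x, layer$rate)
      list(out = dr$out, cache = list(mask = dr$mask))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], prod(d[-1])), cache = list(d = d))
    },
    last_step = {
      d <- dim(x)
      list(out = matrix(x[, d[2], ], d[1], d[3]), cache = list(d = d))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv1d = {
      dz <- if (layer$activation == "relu")
        cpp_relu_bwd(dout, cache$a) else dout
      attr(dz, "dilation") <- layer$dilation
      g <- conv1d_bwd(cache$xin, layer$par$W, dz)
      dx <- g$dx
      if (layer$causal) {
        pad <- (layer$kernel - 1L) * layer$dilation
        dx <- dx[, (pad + 1L):dim(dx)[2], , drop = FALSE]
      }
      list(dx = dx, grads = list(W = g$dW, b = g$db))
    },
    gated_residual = {
      f <- layer$filters
      tu <- cache$tu; sv <- cache$sv
      du <- dout * sv * (1 - tu^2)
      dv <- dout * tu * sv * (1 - sv)
      n <- dim(du)[1]; Tt <- dim(du)[2]
      dz <- array(0, c(n, Tt, 2L * f))
      dz[, , seq_len(f)] <- du
      dz[, , f + seq_len(f)] <- dv
      attr(dz, "dilation") <- layer$dilation
      g <- conv1d_bwd(cache$xin, layer$par$W, dz)
      pad <- (layer$kernel - 1L) * layer$dilation
      dx <- g$dx[, (pad + 1L):dim(g$dx)[2], , drop = FALSE]
      grads <- list(W = g$dW, b = g$db)
      if (is.null(layer$par$P)) {
        dx <- dx + dout
      } else {
        d <- dim(cache$x)
        dres <- matrix(dout, d[1] * d[2], f)
        xm <- matrix(cache$x, d[1] * d[2], d[3])
        grads$P <- crossprod(xm, dres)
        grads$pb <- colSums(dres)
        dx <- dx + array(dres %*% t(layer$par$P), d)
      }
      list(dx = dx, grads = grads)
    },
    dense = {
      dz <- if (layer$activation == "relu")
        cpp_relu_bwd(dout, cache$a) else dout
      list(dx = dz %*% t(layer$par$W),
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    },
    lstm = lstm_backward(layer, cache, dout),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    flatten = list(dx = array(dout, cache$d), grads = NULL),
    last_step = {
      dx <- array(0, cache$d)
      dx[, cache$d[2], ] <- dout
      list(dx = dx, grads = NULL)
    },
    stop("unknown layer type: ", layer$type))
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    fw <- layer_forward(layers[[l]], x, training)
    x <- fw$out
    caches[[l]] <- fw$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[l]], caches[[l]], dout)
    dout <- bw$dx
    grads[l] <- list(bw$grads)  # plain [[<- would drop NULL entries
  }
  list(dx = dout, grads = grads)
}

# ---- LSTM ------------------------------------------------------------------

# gate column blocks, in order: input i, forget f, output o, candidate g.
# sequence in, full sequence out (n, T, units).
lstm_forward <- function(layer, x) {
  d <- dim(x); n <- d[1]; Tt <- d[2]; C <- d[3]
  H <- layer$units
  Wx <- layer$par$Wx; Wh <- layer$par$Wh; b <- layer$par$b
  hseq <- array(0, c(n, Tt, H))
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  gates <- vector("list", Tt); cs <- vector("list", Tt)
  hprev <- vector("list", Tt); cprev <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(x[, t, ], n, C)
    z <- sweep(xt %*% Wx + h %*% Wh, 2, b, "+")
    i <- sigmoid(z[, seq_len(H), drop = FALSE])
    f <- sigmoid(z[, H + seq_len(H), drop = FALSE])
    o <- sigmoid(z[, 2L * H + seq_len(H), drop = FALSE])
    g <- tanh(z[, 3L * H + seq_len(H), drop = FALSE])
    hprev[[t]] <- h; cprev[[t]] <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    hseq[, t, ] <- h
    gates[[t]] <- list(i = i, f = f, o = o, g = g, tc = tc)
  }
  list(out = hseq,
       cache = list(x = x, gates = gates, hprev = hprev, cprev = cprev))
}

lstm_backward <- function(layer, cache, dout) {
  x <- cache$x
  d <- dim(x); n <- d[1]; Tt <- d[2]; C <- d[3]
  H <- layer$units
  Wx <- layer$par$Wx; Wh <- layer$par$Wh
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4L * H)
  dx <- array(0, d)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tt))) {
    gt <- cache$gates[[t]]
    dh <- matrix(dout[, t, ], n, H) + dh_next
    dc <- dh * gt$o * (1 - gt$tc^2) + dc_next
    di <- dc * gt$g
    df <- dc * cache$cprev[[t]]
    do_ <- dh * gt$tc
    dg <- dc * gt$i
    dz <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                do_ * gt$o * (1 - gt$o),
                dg * (1 - gt$g^2))
    xt <- matrix(x[, t, ], n, C)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(cache$hprev[[t]], dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * gt$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- loss and optimizer ----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy over the batch; returns loss and dlogits
softmax_xent <- function(logits, y_onehot) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  list(loss = -sum(y_onehot * log(pmax(p, 1e-12))) / n,
       dlogits = (p - y_onehot) / n)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$par)) return(NULL)
    list(m = lapply(l$par, function(p) array(0, dim(p) %||% length(p))),
         v = lapply(l$par, function(p) array(0, dim(p) %||% length(p))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update over all layers. Mutates the weight and moment arrays in
# place (via the C kernel), so `layers` and `state` must hold arrays private
# to the training loop — see deep_copy_layers().
adam_step <- function(layers, grads, state, t,
                      lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    if (is.null(g) || isTRUE(layers[[l]]$frozen)) next
    for (nm in names(layers[[l]]$par)) {
      gi <- g[[nm]]
      if (is.null(gi)) next
      cpp_adam_inplace(layers[[l]]$par[[nm]], gi,
                       state[[l]]$m[[nm]], state[[l]]$v[[nm]],
                       lr, beta1, beta2, eps, bc1, bc2)
    }
  }
  invisible(NULL)
}

# fresh copies of every weight array, so in-place optimizer updates can
# never reach a caller's model or an earlier snapshot
deep_copy_layers <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$par)) l$par <- lapply(l$par, function(p) p + 0)
    l
  })
}
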