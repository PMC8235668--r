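# Minimal neural-network engine: dense, time-distributed dense, 1-D
# convolution (+ max pooling), LSTM; tanh/selu/sigmoid activations; inverted
# dropout; reverse-mode gradients throughout. Networks here are tiny (<= 11
# hidden layers, <= 64 units), so plain vectorised R is adequate.

SELU_SCALE <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

act_fw <- function(z, name) {
  switch(name,
    tanh = tanh(z),
    selu = ifelse(z > 0, SELU_SCALE * z,
                  SELU_SCALE * SELU_ALPHA * (exp(z) - 1)),
    sigmoid = 1 / (1 + exp(-z)),
    linear = z,
    rlang::abort(paste0("Unknown activation: ", name),
                 class = "gait_config_error")
  )
}

# Derivative d(activation)/dz expressed through the activation output `a`.
act_deriv <- function(a, name) {
  switch(name,
    tanh = 1 - a^2,
    selu = ifelse(a > 0, SELU_SCALE, a + SELU_SCALE * SELU_ALPHA),
    sigmoid = a * (1 - a),
    linear = array(1, dim = dim(a) %||% length(a))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

as_mat <- function(x, nr, nc) { dim(x) <- c(nr, nc); x }

# ---- layer constructors (parameters initialised from the current RNG) ----

layer_dense <- function(d_in, units, activation, dropout = 0) {
  list(type = "dense", activation = activation, dropout = dropout,
       params = list(W = glorot(d_in, units, c(d_in, units)),
                     b = numeric(units)))
}

layer_td_dense <- function(c_in, units, activation, dropout = 0) {
  list(type = "td_dense", activation = activation, dropout = dropout,
       params = list(W = glorot(c_in, units, c(c_in, units)),
                     b = numeric(units)))
}

layer_conv <- function(c_in, filters, kernel, activation) {
  list(type = "conv", activation = activation, kernel = kernel,
       params = list(W = glorot(kernel * c_in, filters,
                                c(kernel, c_in, filters)),
                     b = numeric(filters)))
}

layer_pool <- function() list(type = "pool", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

layer_lstm <- function(c_in, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias
  list(type = "lstm", units = units,
       params = list(Wx = glorot(c_in, 4 * units, c(c_in, 4 * units)),
                     Wh = glorot(units, 4 * units, c(units, 4 * units)),
                     b = b))
}

# ---- forward ----

layer_forward <- function(layer, x, training = FALSE) {
  cache <- list(x = x)
  out <- switch(layer$type,
    dense = {
      a <- act_fw(sweep(x %*% layer$params$W, 2, layer$params$b, "+"),
                  layer$activation)
      cache$a <- a
      a
    },
    td_dense = {
      d <- dim(x)  # N x w x c
      m <- as_mat(x, d[1] * d[2], d[3])
      a <- act_fw(sweep(m %*% layer$params$W, 2, layer$params$b, "+"),
                  layer$activation)
      cache$a <- a
      array(a, dim = c(d[1], d[2], ncol(layer$params$W)))
    },
    conv = {
      d <- dim(x); k <- layer$kernel
      wo <- d[2] - k + 1
      f <- dim(layer$params$W)[3]
      z <- matrix(0, d[1] * wo, f)
      for (j in seq_len(k)) {
        xj <- as_mat(x[, j:(j + wo - 1), , drop = FALSE], d[1] * wo, d[3])
        z <- z + xj %*% as_mat(layer$params$W[j, , ], d[3], f)
      }
      a <- act_fw(sweep(z, 2, layer$params$b, "+"), layer$activation)
      cache$a <- a
      cache$wo <- wo
      array(a, dim = c(d[1], wo, f))
    },
    pool = {
      d <- dim(x)
      wo <- d[2] %/% 2
      if (wo == 0) rlang::abort("Pooling over fewer than 2 time steps",
                                class = "gait_config_error")
      a1 <- x[, seq(1, 2 * wo, by = 2), , drop = FALSE]
      a2 <- x[, seq(2, 2 * wo, by = 2), , drop = FALSE]
      cache$mask <- a1 >= a2
      cache$wo <- wo
      pmax(a1, a2)
    },
    flatten = {
      d <- dim(x)
      as_mat(x, d[1], prod(d[-1]))
    },
    lstm = {
      d <- dim(x); u <- layer$units; n <- d[1]
      h <- matrix(0, n, u); cs <- matrix(0, n, u)
      steps <- vector("list", d[2])
      for (t in seq_len(d[2])) {
        xt <- as_mat(x[, t, , drop = FALSE], n, d[3])
        z <- sweep(xt %*% layer$params$Wx + h %*% layer$params$Wh, 2,
                   layer$params$b, "+")
        ig <- 1 / (1 + exp(-z[, 1:u, drop = FALSE]))
        fg <- 1 / (1 + exp(-z[, (u + 1):(2 * u), drop = FALSE]))
        gg <- tanh(z[, (2 * u + 1):(3 * u), drop = FALSE])
        og <- 1 / (1 + exp(-z[, (3 * u + 1):(4 * u), drop = FALSE]))
        cs_new <- fg * cs + ig * gg
        h_new <- og * tanh(cs_new)
        steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cs,
                           i = ig, f = fg, g = gg, o = og, c = cs_new)
        h <- h_new; cs <- cs_new
      }
      cache$steps <- steps
      h
    },
    rlang::abort(paste0("Unknown layer type: ", layer$type))
  )
  if (training && (layer$dropout %||% 0) > 0 &&
      layer$type %in% c("dense", "td_dense")) {
    keep <- 1 - layer$dropout
    mask <- array(stats::rbinom(length(out), 1, keep) / keep,
                  dim = dim(out) %||% length(out))
    cache$drop_mask <- mask
    out <- out * mask
  }
  list(out = out, cache = cache)
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  cur <- x
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], cur, training = training)
    caches[[i]] <- fw$cache
    cur <- fw$out
  }
  list(logit = as.numeric(cur), caches = caches)
}

# ---- backward ----

layer_backward <- function(layer, cache, dout) {
  if (!is.null(cache$drop_mask)) dout <- dout * cache$drop_mask
  switch(layer$type,
    dense = {
      dz <- dout * act_deriv(cache$a, layer$activation)
      list(grads = list(W = crossprod(cache$x, dz), b = colSums(dz)),
           dx = dz %*% t(layer$params$W))
    },
    td_dense = {
      d <- dim(cache$x)
      u <- ncol(layer$params$W)
      dz <- as_mat(dout, d[1] * d[2], u) * act_deriv(cache$a, layer$activation)
      m <- as_mat(cache$x, d[1] * d[2], d[3])
      dx <- dz %*% t(layer$params$W)
      list(grads = list(W = crossprod(m, dz), b = colSums(dz)),
           dx = array(dx, dim = d))
    },
    conv = {
      d <- dim(cache$x); k <- layer$kernel
      wo <- cache$wo; f <- dim(layer$params$W)[3]
      dz <- as_mat(dout, d[1] * wo, f) * act_deriv(cache$a, layer$activation)
      dW <- array(0, dim = dim(layer$params$W))
      dx <- array(0, dim = d)
      for (j in seq_len(k)) {
        xj <- as_mat(cache$x[, j:(j + wo - 1), , drop = FALSE],
                     d[1] * wo, d[3])
        dW[j, , ] <- crossprod(xj, dz)
        dxj <- dz %*% t(as_mat(layer$params$W[j, , ], d[3], f))
        dx[, j:(j + wo - 1), ] <- dx[, j:(j + wo - 1), , drop = FALSE] +
          array(dxj, dim = c(d[1], wo, d[3]))
      }
      list(grads = list(W = dW, b = colSums(dz)), dx = dx)
    },
    pool = {
      d <- dim(cache$x)
      wo <- cache$wo
      dx <- array(0, dim = d)
      dx[, seq(1, 2 * wo, by = 2), ] <- dout * cache$mask
      dx[, seq(2, 2 * wo, by = 2), ] <- dout * !cache$mask
      list(grads = list(), dx = dx)
    },
    flatten = {
      list(grads = list(), dx = array(dout, dim = dim(cache$x)))
    },
    lstm = {
      d <- dim(cache$x); u <- layer$units; n <- d[1]
      dWx <- array(0, dim = dim(layer$params$Wx))
      dWh <- array(0, dim = dim(layer$params$Wh))
      db <- numeric(4 * u)
      dx <- array(0, dim = d)
      dh <- dout
      dc <- matrix(0, n, u)
      for (t in rev(seq_len(d[2]))) {
        s <- cache$steps[[t]]
        tc <- tanh(s$c)
        do_ <- dh * tc
        dc <- dc + dh * s$o * (1 - tc^2)
        di <- dc * s$g
        df <- dc * s$c_prev
        dg <- dc * s$i
        dzi <- di * s$i * (1 - s$i)
        dzf <- df * s$f * (1 - s$f)
        dzg <- dg * (1 - s$g^2)
        dzo <- do_ * s$o * (1 - s$o)
        dz <- cbind(dzi, dzf, dzg, dzo)
        dWx <- dWx + crossprod(s$xt, dz)
        dWh <- dWh + crossprod(s$h_prev, dz)
        db <- db + colSums(dz)
        dx[, t, ] <- dz %*% t(layer$params$Wx)
        dh <- dz %*% t(layer$params$Wh)
        dc <- dc * s$f
      }
      list(grads = list(Wx = dWx, Wh = dWh, b = db), dx = dx)
    }
  )
}

nn_backward <- function(net, caches, dlogit) {
  grads <- vector("list", length(net$layers))
  dcur <- matrix(dlogit, ncol = 1)
  for (i in rev(seq_along(net$layers))) {
    bk <- layer_backward(net$layers[[i]], caches[[i]], dcur)
    grads[[i]] <- bk$grads
    dcur <- bk$dx
  }
  grads
}

# ---- optimizers ----

opt_init <- function(net, optimizer, learning_rate) {
  slots <- purrr::map(net$layers, function(l) {
    purrr::map(l$params, function(p) {
      list(m = array(0, dim = dim(p) %||% length(p)),
           v = array(0, dim = dim(p) %||% length(p)))
    })
  })
  list(name = optimizer, lr = learning_rate, t = 0L, slots = slots)
}

opt_step <- function(net, grads, state) {
  state$t <- state$t + 1L
  for (i in seq_along(net$layers)) {
    for (pn in names(net$layers[[i]]$params)) {
      g <- grads[[i]][[pn]]
      if (is.null(g)) next
      p <- net$layers[[i]]$params[[pn]]
      slot <- state$slots[[i]][[pn]]
      upd <- switch(state$name,
        sgd = state$lr * g,
        rmsprop = {
          slot$v <- 0.9 * slot$v + 0.1 * g^2
          state$lr * g / (sqrt(slot$v) + 1e-8)
        },
        adam = {
          slot$m <- 0.9 * slot$m + 0.1 * g
          slot$v <- 0.999 * slot$v + 0.001 * g^2
          mh <- slot$m / (1 - 0.9^state$t)
          vh <- slot$v / (1 - 0.999^state$t)
          state$lr * mh / (sqrt(vh) + 1e-8)
        },
        rlang::abort(paste0("Unknown optimizer: ", state$name),
                     class = "gait_config_error")
      )
      net$layers[[i]]$params[[pn]] <- p - upd
      state$slots[[i]][[pn]] <- slot
    }
  }
  list(net = net, state = state)
}

net_weights <- function(net) purrr::map(net$layers, "params")

set_net_weights <- function(net, weights) {
  for (i in seq_along(net$layers)) net$layers[[i]]$params <- weights[[i]]
  net
}
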