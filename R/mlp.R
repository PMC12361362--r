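# Internal feed-forward network used as the deep feature extractor of the
# detector.  Small dense nets on tabular data: plain matrix algebra with
# Adam updates is all that is needed, and keeps the package dependency-free.

activation_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) * 1),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a)),
    tanh = list(f = base::tanh,
                df = function(z, a) 1 - a^2),
    leaky_relu = list(f = function(z) ifelse(z > 0, z, 0.01 * z),
                      df = function(z, a) ifelse(z > 0, 1, 0.01)),
    elu = list(f = function(z) ifelse(z > 0, z, exp(z) - 1),
               df = function(z, a) ifelse(z > 0, 1, a + 1)),
    linear = list(f = identity, df = function(z, a) 1),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE)
  )
}

#' Map an activation gene to an activation name
#'
#' The activation hyperparameter is searched over the integer range
#' `[1, 5]`; this fixed table decodes the gene.
#'
#' @param index Integer in 1..5.
#' @return One of `"relu"`, `"sigmoid"`, `"tanh"`, `"leaky_relu"`, `"elu"`.
#' @examples
#' activation_from_index(1)
#' @export
activation_from_index <- function(index) {
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 1 || index > 5 || index != round(index)) {
    stop("activation index must be an integer in [1, 5]", call. = FALSE)
  }
  c("relu", "sigmoid", "tanh", "leaky_relu", "elu")[as.integer(index)]
}

mlp_init <- function(sizes) {
  # He-style scaled normal initialization
  layers <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                 nrow = sizes[l], ncol = sizes[l + 1L]),
      b = rep(0, sizes[l + 1L])
    )
  }
  layers
}

mlp_forward <- function(layers, x, act, keep = FALSE) {
  # x: n x d matrix; hidden layers use `act`, output layer sigmoid
  L <- length(layers)
  as_ <- vector("list", L)
  zs <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    z <- a %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(a), length(layers[[l]]$b),
                                      byrow = TRUE)
    fn <- if (l == L) activation_fun("sigmoid") else act
    a <- fn$f(z)
    if (keep) { zs[[l]] <- z; as_[[l]] <- a }
  }
  if (keep) list(out = a, zs = zs, as = as_) else a
}

# One Adam step over a mini-batch with binary cross-entropy loss.
mlp_backward <- function(layers, x, y, act) {
  L <- length(layers)
  fwd <- mlp_forward(layers, x, act, keep = TRUE)
  n <- nrow(x)
  grads <- vector("list", L)
  # BCE + sigmoid output: delta = (p - y) / n
  delta <- (fwd$out - y) / n
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) x else fwd$as[[l - 1L]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      fn <- act
      delta <- (delta %*% t(layers[[l]]$W)) * fn$df(fwd$zs[[l - 1L]], fwd$as[[l - 1L]])
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (l in seq_along(layers)) {
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[l]]$W
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[l]]$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[l]]$b
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[l]]$b^2
    mW_hat <- st$mW / (1 - beta1^t); vW_hat <- st$vW / (1 - beta2^t)
    mb_hat <- st$mb / (1 - beta1^t); vb_hat <- st$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Train the extractor network.  Early stopping monitors loss on a held-out
# stratified fraction (patience in epochs); with monitor_frac = 0 the full
# data is used and stopping falls back to the training loss.
mlp_train <- function(x, y, hidden, activation, learning_rate, epochs,
                      batch_size = 16L, patience = 30L, monitor_frac = 0.2,
                      seed = 1L) {
  x <- as_numeric_matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  act <- activation_fun(activation)
  sizes <- c(ncol(x), hidden, 1L)

  withr::with_seed(seed, {
    n <- nrow(x)
    if (monitor_frac > 0 && n >= 10L) {
      idx1 <- which(y == 1); idx0 <- which(y != 1)
      n_val1 <- max(1L, floor(monitor_frac * length(idx1)))
      n_val0 <- max(1L, floor(monitor_frac * length(idx0)))
      val_idx <- c(sample(idx1, n_val1), sample(idx0, n_val0))
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      tr_idx <- seq_len(n); val_idx <- seq_len(n)
    }
    xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]

    layers <- mlp_init(sizes)
    state <- adam_state(layers)
    t_step <- 0L
    best_loss <- Inf; best_layers <- layers; wait <- 0L
    final_train_loss <- NA_real_

    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(xt))
      for (start in seq(1L, nrow(xt), by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, nrow(xt))]
        grads <- mlp_backward(layers, xt[batch, , drop = FALSE],
                              matrix(yt[batch], ncol = 1L), act)
        t_step <- t_step + 1L
        upd <- adam_update(layers, grads, state, learning_rate, t_step)
        layers <- upd$layers; state <- upd$state
      }
      val_loss <- bce_loss(mlp_forward(layers, xv, act), matrix(yv, ncol = 1L))
      final_train_loss <- bce_loss(mlp_forward(layers, xt, act), matrix(yt, ncol = 1L))
      if (val_loss < best_loss - 1e-9) {
        best_loss <- val_loss; best_layers <- layers; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }

    list(layers = best_layers, activation = activation, sizes = sizes,
         final_train_loss = final_train_loss, monitor_loss = best_loss,
         epochs_run = ep)
  })
}

# Penultimate-layer activations: one row per input row, last-hidden-width
# columns.
mlp_penultimate <- function(net, x) {
  x <- as_numeric_matrix(x)
  if (ncol(x) != net$sizes[1]) {
    stop(sprintf("input has %d columns but the extractor expects %d",
                 ncol(x), net$sizes[1]), call. = FALSE)
  }
  act <- activation_fun(net$activation)
  L <- length(net$layers)
  a <- x
  for (l in seq_len(L - 1L)) {
    z <- a %*% net$layers[[l]]$W + matrix(net$layers[[l]]$b, nrow(a),
                                          length(net$layers[[l]]$b), byrow = TRUE)
    a <- act$f(z)
  }
  a
}

mlp_predict_prob <- function(net, x) {
  act <- activation_fun(net$activation)
  as.vector(mlp_forward(net$layers, as_numeric_matrix(x), act))
}
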