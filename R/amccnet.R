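# Adaptive multi-scale convolutional capsule network for AF-rate regression.
# Forward pass: multi-scale stem -> primary capsules -> dynamic routing ->
# digit-capsule-norm readout.  Training is squared-error gradient descent
# (Adam) over all stem, capsule-conv, transform and readout parameters; the
# routing coupling coefficients are treated as constants during
# backpropagation (the routing loop itself is exact).

amcc_init_params <- function(n_features, hidden_neurons, n_digit, primary_dim,
                             digit_dim, branch_filters) {
  n_caps_channels <- primary_dim * (hidden_neurons %/% primary_dim)
  n_primary <- n_features * (n_caps_channels %/% primary_dim)
  cin <- 3L * branch_filters
  list(
    W3 = matrix(stats::rnorm(3 * branch_filters, sd = 0.3), 3, branch_filters),
    b3 = rep(0, branch_filters),
    W5 = matrix(stats::rnorm(5 * branch_filters, sd = 0.3), 5, branch_filters),
    b5 = rep(0, branch_filters),
    W7 = matrix(stats::rnorm(7 * branch_filters, sd = 0.3), 7, branch_filters),
    b7 = rep(0, branch_filters),
    K = array(stats::rnorm(3 * cin * n_caps_channels, sd = 0.2),
              c(3, cin, n_caps_channels)),
    pb = rep(0, n_caps_channels),
    z = array(stats::rnorm(n_primary * n_digit * digit_dim * primary_dim,
                           sd = 0.2),
              c(n_primary, n_digit, digit_dim, primary_dim)),
    rw = stats::rnorm(n_digit, sd = 0.5),
    rb = 0
  )
}

amcc_forward <- function(par, x, activation, n_digit, primary_dim, digit_dim,
                         routing_iterations, keep = FALSE) {
  act <- activation_fun(activation)
  n_pos <- length(x)
  zs <- list(); as_ <- list()
  patches <- list(k3 = conv1d_patches(x, 3L),
                  k5 = conv1d_patches(x, 5L),
                  k7 = conv1d_patches(x, 7L))
  Wk <- list(k3 = par$W3, k5 = par$W5, k7 = par$W7)
  bk <- list(k3 = par$b3, k5 = par$b5, k7 = par$b7)
  branch_pre <- branch_out <- list()
  for (k in names(patches)) {
    z <- patches[[k]] %*% Wk[[k]] +
      matrix(bk[[k]], n_pos, length(bk[[k]]), byrow = TRUE)
    branch_pre[[k]] <- z
    branch_out[[k]] <- act$f(z)
  }
  U <- do.call(cbind, branch_out)
  P <- caps_conv_forward(U, par$K, par$pb)          # pre-squash channel map
  caps_raw <- caps_group(P, primary_dim)
  V <- squash_rows(caps_raw)
  routed <- caps_route(V, par$z, iterations = routing_iterations)
  norms <- sqrt(rowSums(routed$digit^2))
  a_lin <- sum(par$rw * norms) + par$rb
  p <- stats::plogis(a_lin)
  if (!keep) return(p)
  list(p = p, a_lin = a_lin, norms = norms, routed = routed, V = V,
       caps_raw = caps_raw, P = P, U = U,
       branch_pre = branch_pre, patches = patches)
}

amcc_backward <- function(par, x, y, activation, n_digit, primary_dim,
                          digit_dim, routing_iterations) {
  act <- activation_fun(activation)
  fw <- amcc_forward(par, x, activation, n_digit, primary_dim, digit_dim,
                     routing_iterations, keep = TRUE)
  n_pos <- length(x)
  n_prim <- nrow(fw$V)

  g <- lapply(par, function(p) p * 0)
  dL_dp <- 2 * (fw$p - y)
  da <- dL_dp * fw$p * (1 - fw$p)
  g$rw <- da * fw$norms
  g$rb <- da
  dnorm <- da * par$rw

  digit <- fw$routed$digit
  coupling <- fw$routed$coupling
  u_hat <- fw$routed$u_hat
  dV <- fw$V * 0
  for (b in seq_len(n_digit)) {
    vb <- digit[b, ]
    nb <- fw$norms[b]
    dvb <- if (nb > 0) dnorm[b] * vb / nb else rep(0, digit_dim)
    ub <- matrix(u_hat[, b, ], nrow = n_prim)
    e_b <- colSums(coupling[, b] * ub)
    de <- squash_jvp(e_b, dvb)
    du <- outer(coupling[, b], de)               # n_prim x digit_dim
    # g$z[a,b,i,j] += du[a,i] * V[a,j]; dV[a,j] += sum_i du[a,i] z[a,b,i,j]
    du_exp <- outer(du, rep(1, primary_dim))     # (a, i, j) = du[a, i]
    V_exp <- aperm(outer(fw$V, rep(1, digit_dim)), c(1, 3, 2))  # (a,i,j)=V[a,j]
    zb <- array(par$z[, b, , ], c(n_prim, digit_dim, primary_dim))
    g$z[, b, , ] <- g$z[, b, , ] + du_exp * V_exp
    dV <- dV + colSums(aperm(zb * du_exp, c(2, 1, 3)))
  }

  dP <- caps_ungroup(squash_jvp_rows(fw$caps_raw, dV), n_pos, primary_dim)

  Upad <- rbind(0, fw$U, 0)
  dUpad <- Upad * 0
  for (t in 1:3) {
    rows <- t:(t + n_pos - 1L)
    g$K[t, , ] <- g$K[t, , ] + crossprod(Upad[rows, , drop = FALSE], dP)
    dUpad[rows, ] <- dUpad[rows, ] + dP %*% t(par$K[t, , ])
  }
  g$pb <- colSums(dP)
  dU <- dUpad[2:(n_pos + 1L), , drop = FALSE]

  nb_f <- ncol(par$W3)
  cols <- list(k3 = seq_len(nb_f), k5 = nb_f + seq_len(nb_f),
               k7 = 2L * nb_f + seq_len(nb_f))
  Wn <- c(k3 = "W3", k5 = "W5", k7 = "W7")
  bn <- c(k3 = "b3", k5 = "b5", k7 = "b7")
  for (k in names(cols)) {
    dout <- dU[, cols[[k]], drop = FALSE]
    z <- fw$branch_pre[[k]]
    dz <- dout * act$df(z, act$f(z))
    g[[Wn[k]]] <- g[[Wn[k]]] + crossprod(fw$patches[[k]], dz)
    g[[bn[k]]] <- g[[bn[k]]] + colSums(dz)
  }
  list(grads = g, loss = (fw$p - y)^2, pred = fw$p)
}

adam_list_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0))
}

adam_list_update <- function(par, grads, state, lr, t, beta1 = 0.9,
                             beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    m_hat <- state$m[[nm]] / (1 - beta1^t)
    v_hat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(par = par, state = state)
}

#' Multi-scale convolutional capsule network for AF-rate regression
#'
#' Trains the capsule regressor on tabular features: three parallel 1-D
#' convolution branches (kernel lengths 3/5/7, "same" padding) over the
#' feature axis feed a linear capsule convolution whose channels are
#' regrouped into squashed primary capsules; dynamic routing produces digit
#' capsules whose norms pass through an affine-plus-sigmoid readout giving
#' the normalized AF rate in `[0, 1]`. All parameters are trained by Adam
#' on the mean squared error; the routing coupling coefficients are treated
#' as constants in the gradient (the forward routing loop is exact).
#'
#' @param x Feature matrix (at least 7 columns; columns are standardized
#'   internally and the scaling is stored for prediction).
#' @param af Numeric AF-rate targets in `[0, 1]`, one per row of `x`; at
#'   least 20 rows.
#' @param learning_rate Adam learning rate (the tunable gene, range
#'   `[0.01, 0.99]` under [tune_amccnet()]).
#' @param hidden_neurons Primary-capsule channel budget in `[5, 255]`; the
#'   capsule convolution emits `primary_dim * floor(hidden_neurons /
#'   primary_dim)` channels, so values below `primary_dim` are invalid.
#' @param activation Stem activation (name or index 1..5).
#' @param epochs,batch_size Training budget (defaults 100 / 16).
#' @param n_digit Number of digit capsules (default 4).
#' @param primary_dim,digit_dim Capsule pose dimensions (defaults 8 / 16).
#' @param routing_iterations Dynamic-routing iterations (default 3).
#' @param branch_filters Channels per stem branch (default 4).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `"amccnet"` with the trained parameters,
#'   architecture settings, per-epoch training RMSE and the input scaling.
#' @examples
#' d <- simulate_heart_data(n_rows = 40, class_counts = c(20, 20), seed = 5)
#' d <- attach_af_rate(d, seed = 5)
#' x <- as.matrix(d[, 1:8])
#' fit <- amccnet(x, d$af_rate, hidden_neurons = 8, epochs = 3, seed = 5)
#' head(predict(fit, x))
#' @export
amccnet <- function(x, af, learning_rate = 0.01, hidden_neurons = 16L,
                    activation = "relu", epochs = 100L, batch_size = 16L,
                    n_digit = 4L, primary_dim = 8L, digit_dim = 16L,
                    routing_iterations = 3L, branch_filters = 4L, seed = 1L) {
  x <- as_numeric_matrix(x)
  if (ncol(x) < 7L) {
    stop("need at least 7 feature columns (largest stem kernel)", call. = FALSE)
  }
  if (nrow(x) < 20L) stop("need at least 20 training rows", call. = FALSE)
  if (!all(is.finite(af))) stop("AF targets contain non-finite values", call. = FALSE)
  if (any(af < 0 | af > 1)) stop("AF targets must lie in [0, 1]", call. = FALSE)
  hidden_neurons <- as.integer(round(hidden_neurons))
  if (hidden_neurons < primary_dim) {
    stop("hidden_neurons must be at least the primary capsule dimension",
         call. = FALSE)
  }
  if (is.numeric(activation) && !is.character(activation)) {
    activation <- activation_from_index(activation)
  }

  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)

  withr::with_seed(seed, {
    par <- amcc_init_params(ncol(x), hidden_neurons, n_digit, primary_dim,
                            digit_dim, branch_filters)
    state <- adam_list_init(par)
    t_step <- 0L
    n <- nrow(xs)
    epoch_rmse <- numeric(epochs)
    best_par <- par
    best_rmse <- Inf
    for (ep in seq_len(epochs)) {
      # inverse-time decay to a tenth of the base rate by the last epoch
      lr_ep <- learning_rate / (1 + 9 * (ep - 1) / max(1, epochs - 1))
      ord <- sample(n)
      sq_err <- 0
      for (start in seq(1L, n, by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, n)]
        acc <- NULL
        for (i in batch) {
          bw <- amcc_backward(par, xs[i, ], af[i], activation, n_digit,
                              primary_dim, digit_dim, routing_iterations)
          sq_err <- sq_err + bw$loss
          if (is.null(acc)) {
            acc <- bw$grads
          } else {
            for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bw$grads[[nm]]
          }
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
        t_step <- t_step + 1L
        upd <- adam_list_update(par, acc, state, lr_ep, t_step)
        par <- upd$par; state <- upd$state
      }
      epoch_rmse[ep] <- sqrt(sq_err / n)
      # snapshot the best epoch so an oscillating end of training cannot
      # discard an earlier good fit
      if (epoch_rmse[ep] < best_rmse) {
        best_rmse <- epoch_rmse[ep]
        best_par <- par
      }
    }
    par <- best_par

    structure(list(
      par = par,
      hyperparams = list(learning_rate = learning_rate,
                         hidden_neurons = hidden_neurons,
                         activation = activation),
      arch = list(n_digit = n_digit, primary_dim = primary_dim,
                  digit_dim = digit_dim,
                  routing_iterations = routing_iterations,
                  branch_filters = branch_filters,
                  n_features = ncol(x)),
      center = center, scale = scale_,
      epoch_rmse = epoch_rmse,
      train_rmse = best_rmse,
      seed = seed
    ), class = "amccnet")
  })
}

#' Predict AF rates
#'
#' @param object A fitted `"amccnet"` model.
#' @param newdata Feature matrix with the training columns.
#' @param ... Ignored.
#' @return Numeric vector of predicted AF rates in `[0, 1]`.
#' @export
predict.amccnet <- function(object, newdata, ...) {
  x <- as_numeric_matrix(newdata)
  if (ncol(x) != object$arch$n_features) {
    stop(sprintf("newdata has %d columns but the model expects %d",
                 ncol(x), object$arch$n_features), call. = FALSE)
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  vapply(seq_len(nrow(xs)), function(i) {
    amcc_forward(object$par, xs[i, ], object$hyperparams$activation,
                 object$arch$n_digit, object$arch$primary_dim,
                 object$arch$digit_dim, object$arch$routing_iterations)
  }, numeric(1))
}

#' @export
print.amccnet <- function(x, ...) {
  hp <- x$hyperparams; ar <- x$arch
  n_channels <- ar$primary_dim * (hp$hidden_neurons %/% ar$primary_dim)
  cat("Multi-scale convolutional capsule AF-rate regressor\n")
  cat(sprintf("  stem: 3 branches (k = 3/5/7) x %d channels, %s activation, lr %.3g\n",
              ar$branch_filters, hp$activation, hp$learning_rate))
  cat(sprintf("  capsules: %d primary (dim %d, %d channels) -> %d digit (dim %d), %d routing iterations\n",
              ar$n_features * n_channels %/% ar$primary_dim, ar$primary_dim,
              n_channels, ar$n_digit, ar$digit_dim, ar$routing_iterations))
  cat(sprintf("  final training RMSE: %.4f\n", x$train_rmse))
  if (!is.null(x$tuning)) {
    cat(sprintf("  tuned by EAVSRO: validation RMSE %.4f\n", x$tuning$best_fitness))
  }
  invisible(x)
}

#' AF-rate tuning objective: validation RMSE
#'
#' @param actual,predicted Numeric AF-rate vectors of equal length.
#' @return Root mean squared error (see [rmse()]).
#' @export
af_fitness <- function(actual, predicted) rmse(actual, predicted)

#' Tune the AF-rate regressor with ship-rescue optimization
#'
#' Runs EAVSRO over the 3-gene hyperparameter space (learning rate
#' `[0.01, 0.99]`, primary-capsule channel budget `[5, 255]`, stem
#' activation index `[1, 5]`) minimizing held-out RMSE, then retrains at
#' the best genome on all rows. Hyperparameter draws below the minimum
#' capsule budget fail training and score worst-possible fitness.
#'
#' @inheritParams amccnet
#' @param pop_size,max_iter Optimizer budget.
#' @param ... Passed through to [amccnet()].
#' @return An `"amccnet"` model with a `tuning` element (optimizer trace,
#'   selected hyperparameters, validation RMSE).
#' @export
tune_amccnet <- function(x, af, pop_size = 10L, max_iter = 50L, seed = 1L,
                         epochs = 60L, ...) {
  x <- as_numeric_matrix(x)
  n <- nrow(x)
  tr_idx <- withr::with_seed(child_seed(seed, 11L), sort(sample(n, floor(0.8 * n))))
  va_idx <- setdiff(seq_len(n), tr_idx)
  train_seed <- child_seed(seed, 12L)

  decode_hp <- function(genes) {
    list(learning_rate = genes[1],
         hidden_neurons = as.integer(round(clamp_to_bounds(genes[2], 5, 255))),
         activation = activation_from_index(round(clamp_to_bounds(genes[3], 1, 5))))
  }
  objective <- function(genes) {
    hp <- decode_hp(genes)
    tryCatch({
      m <- amccnet(x[tr_idx, , drop = FALSE], af[tr_idx],
                   learning_rate = hp$learning_rate,
                   hidden_neurons = hp$hidden_neurons,
                   activation = hp$activation,
                   epochs = epochs, seed = train_seed, ...)
      af_fitness(af[va_idx], predict(m, x[va_idx, , drop = FALSE]))
    }, error = function(e) 1e12)
  }

  opt <- sro_optimize(objective, lower = c(0.01, 5, 1), upper = c(0.99, 255, 5),
                      pop_size = pop_size, max_iter = max_iter, seed = seed)
  hp <- decode_hp(opt$best_par)
  model <- amccnet(x, af, learning_rate = hp$learning_rate,
                   hidden_neurons = hp$hidden_neurons,
                   activation = hp$activation,
                   epochs = epochs, seed = train_seed, ...)
  model$tuning <- list(best_fitness = opt$best_fitness,
                       best_genes = opt$best_par,
                       hyperparams = hp,
                       trace = opt$trace,
                       seed = seed)
  model
}
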