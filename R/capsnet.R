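#' Capsule squash nonlinearity
#'
#' Rescales a capsule pose vector `e` to
#' `(||e||^2 / (1 + ||e||^2)) * (e / ||e||)`: the direction is preserved
#' and the norm is compressed below 1, so a capsule's length can be read as
#' a presence probability. The zero vector maps to zero (the continuous
#' extension).
#'
#' @param e Finite numeric vector.
#' @return Vector parallel to `e` with norm `||e||^2 / (1 + ||e||^2)`.
#' @examples
#' sqrt(sum(squash(c(1, 0))^2))        # 0.5
#' sqrt(sum(squash(c(3, 0, 0))^2))     # 0.9
#' @export
squash <- function(e) {
  if (!all(is.finite(e))) stop("squash requires finite input", call. = FALSE)
  r2 <- sum(e^2)
  if (r2 == 0) return(e)
  e * (sqrt(r2) / (1 + r2))   # = (r^2/(1+r^2)) * e/r
}

# Row-wise squash of a capsule matrix (one capsule per row).
squash_rows <- function(M) {
  r2 <- rowSums(M^2)
  f <- ifelse(r2 > 0, sqrt(r2) / (1 + r2), 0)
  M * f
}

# Row-wise squash Jacobian-vector product: row a of the result is the
# squash JVP at E[a, ] applied to G[a, ].
squash_jvp_rows <- function(E, G) {
  r2 <- rowSums(E^2)
  r <- sqrt(r2)
  m <- ifelse(r2 > 0, r / (1 + r2), 0)
  dm_over_r <- ifelse(r2 > 0, (1 - r2) / ((1 + r2)^2 * r), 0)
  m * G + (dm_over_r * rowSums(E * G)) * E
}

# Jacobian-vector product of squash at e applied to g (used by backprop).
squash_jvp <- function(e, g) {
  r2 <- sum(e^2)
  if (r2 == 0) return(g * 0)
  r <- sqrt(r2)
  m <- r / (1 + r2)
  dm <- (1 - r2) / (1 + r2)^2
  m * g + (dm / r) * sum(e * g) * e
}

# Cross-correlation of a 1-D signal with a kernel under "same" zero padding.
conv1d_same <- function(x, kernel) {
  k <- length(kernel)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(k)) out <- out + kernel[t] * xp[t:(t + n - 1L)]
  out
}

# Patch matrix for a length-k same-padded window: row `pos` holds the
# window of x feeding output position pos.  Shared by forward and backward.
conv1d_patches <- function(x, k) {
  half <- (k - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  n <- length(x)
  out <- matrix(0, n, k)
  for (t in seq_len(k)) out[, t] <- xp[t:(t + n - 1L)]
  out
}

#' Multi-scale convolutional stem
#'
#' Cross-correlates a 1-D feature vector with three parallel filter banks of
#' kernel lengths 3, 5 and 7 under "same" zero padding, applies the stem
#' activation per branch, and concatenates the branch outputs channel-wise,
#' so fine-grained and broader structural patterns over the feature axis are
#' captured side by side.
#'
#' @param x Numeric feature vector, length at least 7 (the largest kernel).
#' @param filters Named list of filter banks; element `"k3"`, `"k5"`, `"k7"`
#'   is a `kernel_length x n_channels` matrix.
#' @param activation Activation name applied branch-wise (default
#'   `"linear"`).
#' @return A list with `branch_outputs` (one positions-x-channels matrix per
#'   kernel size) and `fused` (their column-wise concatenation).
#' @examples
#' f <- list(k3 = matrix(c(1, 1, 1), 3, 1),
#'           k5 = matrix(0, 5, 1), k7 = matrix(0, 7, 1))
#' multiscale_conv(c(1, 2, 3, 4, 5, 6, 7), f)$branch_outputs$k3
#' @export
multiscale_conv <- function(x, filters, activation = "linear") {
  if (length(x) < 7L) {
    stop("input must be at least as long as the largest kernel (7)", call. = FALSE)
  }
  act <- activation_fun(activation)
  branch_outputs <- lapply(filters, function(W) {
    patches <- conv1d_patches(x, nrow(W))
    act$f(patches %*% W)
  })
  list(branch_outputs = branch_outputs,
       fused = do.call(cbind, branch_outputs))
}

#' Primary capsule layer
#'
#' Applies one further (linear, kernel length 3, same padding) convolution
#' over the fused multi-scale map, regroups the output channels at every
#' position into pose vectors of `capsule_dim` components, and squashes
#' each, producing the primary capsule set.
#'
#' @param fused Positions-x-channels matrix from [multiscale_conv()].
#' @param kernel Array of dim `c(3, in_channels, out_channels)`;
#'   `out_channels` must be a multiple of `capsule_dim`.
#' @param bias Numeric vector of length `out_channels`.
#' @param capsule_dim Pose-vector dimension (default 8).
#' @return A matrix of squashed capsules, one per row
#'   (`positions * out_channels / capsule_dim` rows, `capsule_dim` columns).
#' @export
primary_capsules <- function(fused, kernel, bias, capsule_dim = 8L) {
  cout <- dim(kernel)[3]
  if (cout %% capsule_dim != 0L) {
    stop("capsule conv channels must be a multiple of capsule_dim", call. = FALSE)
  }
  pre <- caps_conv_forward(fused, kernel, bias)
  squash_rows(caps_group(pre, capsule_dim))
}

caps_conv_forward <- function(U, kernel, bias) {
  n <- nrow(U)
  Upad <- rbind(0, U, 0)   # kernel length 3, pad 1
  out <- matrix(bias, n, length(bias), byrow = TRUE)
  for (t in 1:3) out <- out + Upad[t:(t + n - 1L), , drop = FALSE] %*% kernel[t, , ]
  out
}

# Regroup a positions x channels activation matrix into capsules: capsule
# (pos, g) takes channels (g-1)*dim + 1 .. g*dim at position pos.
caps_group <- function(P, capsule_dim) {
  n_pos <- nrow(P)
  groups <- ncol(P) %/% capsule_dim
  out <- matrix(0, n_pos * groups, capsule_dim)
  for (g in seq_len(groups)) {
    out[(g - 1L) * n_pos + seq_len(n_pos), ] <-
      P[, (g - 1L) * capsule_dim + seq_len(capsule_dim), drop = FALSE]
  }
  out
}

caps_ungroup <- function(caps, n_pos, capsule_dim) {
  groups <- nrow(caps) %/% n_pos
  P <- matrix(0, n_pos, groups * capsule_dim)
  for (g in seq_len(groups)) {
    P[, (g - 1L) * capsule_dim + seq_len(capsule_dim)] <-
      caps[(g - 1L) * n_pos + seq_len(n_pos), , drop = FALSE]
  }
  P
}

#' Dynamic routing by agreement
#'
#' Routes primary capsules to digit capsules. Prediction vectors are the
#' linear transforms `u_hat[a, b] = z[a, b] %*% primary[a]`. Routing logits
#' start at zero; each iteration computes coupling coefficients as the
#' per-primary-capsule softmax of the logits, forms each digit input as the
#' coupling-weighted sum of predictions, squashes it, and increments every
#' logit by the dot product between the prediction and the digit output.
#' The loop is fully deterministic.
#'
#' @param primary Matrix of (already squashed) primary capsules, one per
#'   row.
#' @param transforms Array of dim
#'   `c(n_primary, n_digit, digit_dim, primary_dim)`.
#' @param iterations Number of routing iterations (default 3, at least 1).
#' @return A list: `digit` (`n_digit x digit_dim` matrix of output
#'   capsules), `coupling` (final coupling-coefficient matrix), and
#'   `coupling_history` (the coupling matrix at every iteration).
#' @export
caps_route <- function(primary, transforms, iterations = 3L) {
  if (iterations < 1L) stop("routing needs at least one iteration", call. = FALSE)
  dm <- dim(transforms)
  n_prim <- dm[1]; n_digit <- dm[2]; digit_dim <- dm[3]; prim_dim <- dm[4]
  stopifnot(nrow(primary) == n_prim, ncol(primary) == prim_dim)

  u_hat <- array(0, c(n_prim, n_digit, digit_dim))
  for (a in seq_len(n_prim)) {
    # all digit predictions for primary capsule a in one multiply
    za <- matrix(transforms[a, , , ], n_digit * digit_dim, prim_dim)
    u_hat[a, , ] <- matrix(za %*% primary[a, ], n_digit, digit_dim)
  }

  logits <- matrix(0, n_prim, n_digit)
  history <- vector("list", iterations)
  digit <- matrix(0, n_digit, digit_dim)
  coupling <- NULL
  for (it in seq_len(iterations)) {
    ex <- exp(logits - apply(logits, 1L, max))
    coupling <- ex / rowSums(ex)
    history[[it]] <- coupling
    for (b in seq_len(n_digit)) {
      ub <- matrix(u_hat[, b, ], nrow = n_prim)
      e_b <- colSums(coupling[, b] * ub)
      digit[b, ] <- squash(e_b)
    }
    for (b in seq_len(n_digit)) {
      ub <- matrix(u_hat[, b, ], nrow = n_prim)
      logits[, b] <- logits[, b] + as.vector(ub %*% digit[b, ])
    }
  }
  list(digit = digit, coupling = coupling, coupling_history = history,
       u_hat = u_hat)
}

#' Scalar AF-rate readout
#'
#' Maps a digit-capsule set to the normalized atrial-fibrillation rate: the
#' capsule norms (presence strengths) pass through a trained affine map and
#' a sigmoid, so the prediction always lies in `[0, 1]`.
#'
#' @param digit Matrix of digit capsules (one per row).
#' @param weights Affine weights, one per digit capsule.
#' @param bias Affine intercept.
#' @return Scalar rate in `[0, 1]`.
#' @examples
#' af_readout(matrix(0, 4, 16), rep(0, 4), 0)  # sigmoid(0) = 0.5
#' @export
af_readout <- function(digit, weights, bias) {
  norms <- sqrt(rowSums(digit^2))
  stats::plogis(sum(weights * norms) + bias)
}
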