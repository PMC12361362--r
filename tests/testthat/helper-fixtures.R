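# Shared fixtures, generated in code (no stored data files).

# Two well-separated Gaussian blobs in 2-D: linearly separable with margin
# ~ (4 - a few sd); labels 0/1.
make_blobs <- function(n_per_class = 100, sep = 2, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * 2, -sep, sd), n_per_class, 2),
               matrix(stats::rnorm(n_per_class * 2, sep, sd), n_per_class, 2))
    list(x = x, y = rep(0:1, each = n_per_class))
  })
}

# Row-wise squash used only to prepare valid primary-capsule fixtures.
squash_rows_for_test <- function(M) t(apply(M, 1, cardiodetect::squash))

# Independent brute-force routing loop, deliberately written with explicit
# scalar arithmetic (no shared code with caps_route) for oracle comparisons.
brute_force_route <- function(primary, transforms, iterations = 3) {
  n_prim <- nrow(primary)
  dm <- dim(transforms)
  n_digit <- dm[2]; digit_dim <- dm[3]

  sq <- function(v) {
    n2 <- 0
    for (i in seq_along(v)) n2 <- n2 + v[i]^2
    if (n2 == 0) return(v)
    v * (n2 / (1 + n2)) / sqrt(n2)
  }

  u_hat <- array(0, c(n_prim, n_digit, digit_dim))
  for (a in 1:n_prim) {
    for (b in 1:n_digit) {
      for (i in 1:digit_dim) {
        s <- 0
        for (j in seq_len(dm[4])) s <- s + transforms[a, b, i, j] * primary[a, j]
        u_hat[a, b, i] <- s
      }
    }
  }

  logits <- matrix(0, n_prim, n_digit)
  digit <- matrix(0, n_digit, digit_dim)
  history <- list()
  for (it in 1:iterations) {
    coupling <- matrix(0, n_prim, n_digit)
    for (a in 1:n_prim) {
      ex <- exp(logits[a, ] - max(logits[a, ]))
      coupling[a, ] <- ex / sum(ex)
    }
    history[[it]] <- coupling
    for (b in 1:n_digit) {
      e_b <- rep(0, digit_dim)
      for (a in 1:n_prim) e_b <- e_b + coupling[a, b] * u_hat[a, b, ]
      digit[b, ] <- sq(e_b)
    }
    for (b in 1:n_digit) {
      for (a in 1:n_prim) {
        logits[a, b] <- logits[a, b] + sum(u_hat[a, b, ] * digit[b, ])
      }
    }
  }
  list(digit = digit, coupling_history = history)
}
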