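test_that("squash compresses norms below 1 and preserves direction", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(sqrt(sum(squash(c(1, 0))^2)), 0.5)
  expect_equal(sqrt(sum(squash(c(0, 3, 0))^2)), 0.9)
  withr::with_seed(21, {
    for (i in 1:50) {
      e <- stats::rnorm(sample(2:16, 1), sd = stats::runif(1, 0.1, 5))
      s <- squash(e)
      expect_lt(sqrt(sum(s^2)), 1)
      # parallel: cross terms vanish
      expect_equal(s * sqrt(sum(e^2)), e * sqrt(sum(s^2)), tolerance = 1e-12)
    }
  })
  expect_error(squash(c(1, NA)), "finite")
})

test_that("multi-scale convolution matches hand cross-correlation oracles", {
  f_delta <- list(k3 = matrix(c(0, 1, 0), 3, 1),
                  k5 = matrix(c(0, 0, 1, 0, 0), 5, 1),
                  k7 = matrix(c(0, 0, 0, 1, 0, 0, 0), 7, 1))
  x <- c(1.5, -2, 3, 0.5, 4, -1, 2)
  out <- multiscale_conv(x, f_delta)
  # delta kernels: every branch reproduces the input
  expect_equal(out$branch_outputs$k3[, 1], x)
  expect_equal(out$branch_outputs$k5[, 1], x)
  expect_equal(out$branch_outputs$k7[, 1], x)
  expect_equal(ncol(out$fused), 3)
  expect_equal(nrow(out$fused), length(x))

  # box kernel on a ramp, same padding
  f_box <- list(k3 = matrix(1, 3, 1), k5 = matrix(0, 5, 1),
                k7 = matrix(0, 7, 1))
  expect_equal(multiscale_conv(c(1, 2, 3, 4, 5, 6, 7),
                               f_box)$branch_outputs$k3[, 1],
               c(3, 6, 9, 12, 15, 18, 13))

  # zero input, linear activation: zero fused map
  expect_true(all(multiscale_conv(rep(0, 9), f_box)$fused == 0))
  expect_error(multiscale_conv(c(1, 2, 3), f_box), "at least")
})

test_that("primary capsules group channels and bound every norm below 1", {
  withr::with_seed(22, {
    fused <- matrix(stats::rnorm(9 * 12), 9, 12)
    kernel <- array(stats::rnorm(3 * 12 * 16, sd = 0.5), c(3, 12, 16))
    caps <- primary_capsules(fused, kernel, bias = rep(0, 16), capsule_dim = 8)
    # 16 channels / dim 8 = 2 capsule groups per position, 9 positions
    expect_equal(dim(caps), c(18, 8))
    expect_true(all(sqrt(rowSums(caps^2)) < 1))
  })
  # zero map -> zero capsules
  caps0 <- primary_capsules(matrix(0, 8, 4),
                            array(0, c(3, 4, 8)), rep(0, 8), 8)
  expect_true(all(caps0 == 0))
  expect_error(primary_capsules(matrix(0, 8, 4), array(0, c(3, 4, 9)),
                                rep(0, 9), 8), "multiple")
})

test_that("dynamic routing collapses correctly for a single route", {
  withr::with_seed(23, {
    v <- matrix(stats::rnorm(8), 1, 8)
    z <- array(stats::rnorm(16 * 8), c(1, 1, 16, 8))
    for (iters in c(1, 3, 5)) {
      r <- caps_route(v, z, iterations = iters)
      expect_equal(r$digit[1, ], squash(as.vector(z[1, 1, , ] %*% v[1, ])),
                   tolerance = 1e-12)
    }
  })
  expect_error(caps_route(matrix(0, 1, 8), array(0, c(1, 1, 16, 8)),
                          iterations = 0), "at least one")
})

test_that("coupling coefficients normalize at every iteration and routing matches brute force", {
  withr::with_seed(24, {
    for (case in 1:5) {
      n_prim <- sample(2:6, 1)
      n_digit <- sample(2:4, 1)
      primary <- matrix(stats::rnorm(n_prim * 8), n_prim, 8)
      primary <- squash_rows_for_test(primary)
      z <- array(stats::rnorm(n_prim * n_digit * 16 * 8, sd = 0.5),
                 c(n_prim, n_digit, 16, 8))
      got <- caps_route(primary, z, iterations = 3)
      want <- brute_force_route(primary, z, iterations = 3)
      expect_equal(got$digit, want$digit, tolerance = 1e-10)
      for (it in 1:3) {
        expect_equal(rowSums(got$coupling_history[[it]]), rep(1, n_prim),
                     tolerance = 1e-12)
        expect_true(all(got$coupling_history[[it]] >= 0))
        expect_equal(got$coupling_history[[it]], want$coupling_history[[it]],
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("the AF readout is a sigmoid of capsule norms", {
  # zero capsules, zero affine: sigmoid(0) = 0.5
  expect_equal(af_readout(matrix(0, 4, 16), rep(0, 4), 0), 0.5)
  withr::with_seed(25, {
    for (i in 1:20) {
      digit <- matrix(stats::rnorm(4 * 16), 4, 16)
      w <- stats::rnorm(4); b <- stats::rnorm(1)
      r <- af_readout(digit, w, b)
      expect_gte(r, 0); expect_lte(r, 1)
      # monotone in the bias (hence in the affine pre-activation)
      expect_gt(af_readout(digit, w, b + 1), r)
    }
  })
})

test_that("training collapses to a constant target and is seed-deterministic", {
  d <- simulate_heart_data(n_rows = 40, class_counts = c(20, 20), seed = 26)
  x <- as.matrix(d[, 1:8])
  m1 <- amccnet(x, rep(0.7, 40), hidden_neurons = 8, epochs = 25,
                learning_rate = 0.02, seed = 26)
  expect_lt(rmse(rep(0.7, 40), predict(m1, x)), 0.05)

  m2 <- amccnet(x, rep(0.7, 40), hidden_neurons = 8, epochs = 25,
                learning_rate = 0.02, seed = 26)
  expect_identical(m1$train_rmse, m2$train_rmse)
  expect_identical(predict(m1, x), predict(m2, x))

  expect_error(amccnet(x[, 1:5], rep(0.5, 40)), "at least 7")
  expect_error(amccnet(x, rep(2, 40)), "\\[0, 1\\]")
  expect_error(amccnet(x, rep(0.5, 40), hidden_neurons = 5), "at least the primary")
})

test_that("training the synthetic AF function beats the constant-mean baseline", {
  d <- attach_af_rate(simulate_heart_data(n_rows = 120,
                                          class_counts = c(60, 60), seed = 27),
                      seed = 27)
  x <- as.matrix(d[, 1:8])
  m <- amccnet(x, d$af_rate, hidden_neurons = 16, epochs = 40,
               learning_rate = 0.03, seed = 27)
  fit_rmse <- rmse(d$af_rate, predict(m, x))
  base_rmse <- rmse(d$af_rate, rep(mean(d$af_rate), nrow(d)))
  expect_lt(fit_rmse, base_rmse)
})

test_that("AF fitness is RMSE with its standard properties", {
  expect_equal(af_fitness(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(af_fitness(c(3, 4), c(0, 0)), sqrt(12.5))
  # homogeneity: doubling residuals doubles the fitness
  expect_equal(af_fitness(c(6, 8), c(0, 0)), 2 * af_fitness(c(3, 4), c(0, 0)))
  expect_error(af_fitness(numeric(0), numeric(0)), "empty")
})

test_that("AF tuning respects gene ranges and reproduces per seed", {
  d <- attach_af_rate(simulate_heart_data(n_rows = 60,
                                          class_counts = c(30, 30), seed = 28),
                      seed = 28)
  x <- as.matrix(d[, 1:8])
  m1 <- tune_amccnet(x, d$af_rate, pop_size = 3, max_iter = 2, seed = 28,
                     epochs = 6)
  hp <- m1$tuning$hyperparams
  expect_gte(hp$learning_rate, 0.01); expect_lte(hp$learning_rate, 0.99)
  expect_gte(hp$hidden_neurons, 5); expect_lte(hp$hidden_neurons, 255)
  expect_lte(m1$tuning$best_fitness, m1$tuning$trace[1])

  m2 <- tune_amccnet(x, d$af_rate, pop_size = 3, max_iter = 2, seed = 28,
                     epochs = 6)
  expect_identical(m1$tuning$best_genes, m2$tuning$best_genes)
})
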