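#' Clamp a position vector onto box bounds
#'
#' Projects each coordinate of `x` onto the interval `[lower[i], upper[i]]`.
#' Out-of-bounds moves proposed by the rescue update are handled by clamping
#' (rather than reflection) so that repeated runs are deterministic.
#'
#' @param x Numeric vector of positions (genes).
#' @param lower,upper Numeric vectors of per-gene bounds, recycled to the
#'   length of `x` if scalar.
#' @return Numeric vector of the same length as `x`, inside the bounds.
#' @examples
#' clamp_to_bounds(c(-0.2, 0.4, 1.5), 0, 1)
#' @export
clamp_to_bounds <- function(x, lower, upper) {
  if (length(lower) == 1L) lower <- rep(lower, length(x))
  if (length(upper) == 1L) upper <- rep(upper, length(x))
  if (length(lower) != length(x) || length(upper) != length(x)) {
    stop("bounds length does not match position length", call. = FALSE)
  }
  pmin(pmax(x, lower), upper)
}

check_bounds <- function(lower, upper) {
  if (length(lower) != length(upper)) {
    stop("lower and upper bounds must have equal length", call. = FALSE)
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound", call. = FALSE)
  }
  invisible(TRUE)
}

#' Initialize a rescue-ship population
#'
#' Draws `pop_size` candidate positions uniformly within the box bounds.
#'
#' @param lower,upper Numeric vectors of per-gene bounds (equal length).
#' @param pop_size Number of candidates (ships); at least 2.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `pop_size` x `length(lower)` numeric matrix, one candidate per row.
#' @export
sro_population <- function(lower, upper, pop_size = 10L, seed = 1L) {
  check_bounds(lower, upper)
  if (pop_size < 2L) stop("pop_size must be at least 2", call. = FALSE)
  d <- length(lower)
  withr::with_seed(seed, {
    matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                        rep(upper, each = pop_size)),
           nrow = pop_size, ncol = d)
  })
}

#' Fitness-adaptive step ratio
#'
#' The enhancement that distinguishes EAVSRO from plain ship-rescue
#' optimization: the uniform random step coefficient is replaced by the ratio
#' `v = worst / (center + worst + best)` computed from the current
#' population's fitness spread, where `center` is the population mean
#' fitness. For non-negative fitness values `v` always lies in `[0, 1]`.
#'
#' @param best,worst,center Non-negative population fitness summaries
#'   (minimum, maximum, and mean objective value).
#' @return A scalar in `[0, 1]`. A fully degenerate population (all three
#'   summaries zero) returns 0 with a warning.
#' @examples
#' adaptive_step_ratio(best = 0.5, worst = 4, center = 2) # 4 / 6.5
#' @export
adaptive_step_ratio <- function(best, worst, center) {
  stopifnot(is.finite(best), is.finite(worst), is.finite(center))
  if (best < 0 || worst < 0 || center < 0) {
    stop("adaptive step ratio requires non-negative fitness summaries", call. = FALSE)
  }
  den <- center + worst + best
  if (den <= 0) {
    warning("degenerate population: all fitness summaries are zero; v = 0")
    return(0)
  }
  worst / den
}

#' One ship-rescue position update
#'
#' Moves a candidate relative to the prey (population-best) position. When
#' the prey is strictly fitter, the ship searches around the prey:
#' `x + v * (q - I * x)` with an intensity coefficient `I` drawn uniformly
#' from \{1, 2\} per gene; otherwise it retreats along `x + v * (x - q)`.
#' The result is clamped onto the bounds.
#'
#' @param x Numeric candidate position.
#' @param x_fit Its objective value.
#' @param prey Numeric prey position (same length).
#' @param prey_fit Prey objective value.
#' @param v Step ratio in `[0, 1]` (see [adaptive_step_ratio()]).
#' @param lower,upper Bounds used for the final clamp.
#' @param intensity Optional integer vector of per-gene intensity
#'   coefficients in \{1, 2\}; drawn randomly when `NULL`. Injectable for
#'   deterministic tests.
#' @return The updated (clamped) position vector.
#' @export
sro_step <- function(x, x_fit, prey, prey_fit, v, lower, upper, intensity = NULL) {
  if (!is.finite(x_fit) || !is.finite(prey_fit)) {
    stop("candidate and prey must be evaluated before a rescue step", call. = FALSE)
  }
  stopifnot(length(x) == length(prey), v >= 0, v <= 1)
  if (prey_fit < x_fit) {
    if (is.null(intensity)) intensity <- sample(c(1, 2), length(x), replace = TRUE)
    new_x <- x + v * (prey - intensity * x)
  } else {
    new_x <- x + v * (x - prey)
  }
  clamp_to_bounds(new_x, lower, upper)
}

#' Enhanced adaptive-velocity ship-rescue optimization (EAVSRO)
#'
#' Population minimizer over a box-bounded real search space. Each
#' generation recomputes the fitness-adaptive step ratio `v` from the
#' population's best/worst/mean objective values (shared by every candidate
#' in that generation), moves every ship with [sro_step()] toward or away
#' from the current population best (the "prey"), and accepts a move only
#' when it improves the objective (greedy elitism), so the best-fitness
#' trace is monotonically non-increasing.
#'
#' @param objective Function mapping a gene vector to a finite scalar to be
#'   minimized (non-negative for the adaptive ratio to be well defined).
#' @param lower,upper Per-gene bounds.
#' @param pop_size Population size (default 10).
#' @param max_iter Number of generations (default 50).
#' @param seed Integer seed; the full run is reproducible given the seed,
#'   even when `objective` seeds its own internal RNG.
#' @param adaptive If `FALSE`, fall back to the baseline algorithm in which
#'   the step ratio is drawn uniformly from `[0, 1]` each generation.
#' @param intensity Optional fixed per-gene intensity coefficients forwarded
#'   to [sro_step()]; used by tests.
#' @return An object of class `"sro"`: a list with `best_par`,
#'   `best_fitness`, `trace` (best fitness after each generation),
#'   `population`, `fitness`, `evaluations` and the call parameters.
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- sro_optimize(sphere, lower = rep(-5, 3), upper = rep(5, 3), seed = 3)
#' fit
#' @export
sro_optimize <- function(objective, lower, upper, pop_size = 10L, max_iter = 50L,
                         seed = 1L, adaptive = TRUE, intensity = NULL) {
  check_bounds(lower, upper)
  if (pop_size < 2L) stop("pop_size must be at least 2", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be at least 1", call. = FALSE)
  d <- length(lower)

  eval_obj <- function(par, where) {
    f <- isolate_rng(objective(par))
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      stop(sprintf("objective returned a non-finite value at %s: [%s]",
                   where, paste(signif(par, 4), collapse = ", ")), call. = FALSE)
    }
    f
  }

  withr::with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                               rep(upper, each = pop_size)),
                  nrow = pop_size, ncol = d)
    fit <- numeric(pop_size)
    for (j in seq_len(pop_size)) fit[j] <- eval_obj(pop[j, ], "initialization")
    n_eval <- pop_size

    trace <- numeric(max_iter)
    for (it in seq_len(max_iter)) {
      best_idx <- which.min(fit)
      prey <- pop[best_idx, ]
      prey_fit <- fit[best_idx]
      v <- if (adaptive) {
        adaptive_step_ratio(best = min(fit), worst = max(fit), center = mean(fit))
      } else {
        stats::runif(1)
      }
      for (j in seq_len(pop_size)) {
        cand <- sro_step(pop[j, ], fit[j], prey, prey_fit, v, lower, upper,
                         intensity = intensity)
        cand_fit <- eval_obj(cand, sprintf("generation %d", it))
        n_eval <- n_eval + 1L
        if (cand_fit < fit[j]) {
          pop[j, ] <- cand
          fit[j] <- cand_fit
        }
      }
      trace[it] <- min(fit)
    }

    best_idx <- which.min(fit)
    structure(list(
      best_par = pop[best_idx, ],
      best_fitness = fit[best_idx],
      trace = trace,
      population = pop,
      fitness = fit,
      evaluations = n_eval,
      pop_size = pop_size,
      max_iter = max_iter,
      seed = seed,
      adaptive = adaptive
    ), class = "sro")
  })
}

#' @export
print.sro <- function(x, ...) {
  cat("Ship-rescue optimization (", if (x$adaptive) "adaptive v" else "uniform v",
      ")\n", sep = "")
  cat(sprintf("  population %d, %d generations, %d objective evaluations\n",
              x$pop_size, x$max_iter, x$evaluations))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  cat("  best position:", paste(signif(x$best_par, 5), collapse = " "), "\n")
  invisible(x)
}

#' Plot an optimizer convergence trace
#'
#' @param x An `"sro"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sro <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "s",
                 xlab = "generation", ylab = "best fitness", ...)
  invisible(x)
}

#' Convergence trace as a data frame
#'
#' @param x An `"sro"` fit.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A data frame with columns `iteration` and `best_fitness`, suitable
#'   for writing to CSV.
#' @export
as.data.frame.sro <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(iteration = seq_along(x$trace), best_fitness = x$trace)
}
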