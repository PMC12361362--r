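#' Decode a selection genome into feature indices and weights
#'
#' A selection genome carries K real-valued feature genes (each in
#' `[1, n_features]`) paired with K weight genes (each in `[0.01, 0.99]`).
#' Feature genes are rounded to the nearest column index; duplicate indices
#' are dropped keeping the first occurrence together with its paired weight,
#' so the decoded selection can be smaller than K but is never empty.
#'
#' @param feature_genes Real vector of feature genes.
#' @param weight_genes Real vector of paired weight genes (same length).
#' @param n_features Number of columns in the feature table.
#' @return A list with integer `indices` and numeric `weights` of equal
#'   length.
#' @examples
#' decode_selection(c(2.4, 2.6, 7.9), c(0.5, 0.6, 0.7), n_features = 10)
#' @export
decode_selection <- function(feature_genes, weight_genes, n_features) {
  if (length(feature_genes) == 0L) {
    stop("selection genome is empty", call. = FALSE)
  }
  if (length(feature_genes) != length(weight_genes)) {
    stop("feature and weight genes must have equal length", call. = FALSE)
  }
  idx <- pmin(pmax(as.integer(round(feature_genes)), 1L), as.integer(n_features))
  keep <- !duplicated(idx)
  list(indices = idx[keep], weights = weight_genes[keep])
}

#' Chi-square statistic between observed and expected counts
#'
#' `sum((observed - expected)^2 / expected)` over aligned cells.
#'
#' @param observed Non-negative numeric vector of observed counts.
#' @param expected Positive numeric vector of expected counts.
#' @return A non-negative scalar; 0 iff observed equals expected.
#' @examples
#' chi_square_score(c(10, 20), c(15, 15))
#' @export
chi_square_score <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have equal length", call. = FALSE)
  }
  bad <- which(expected <= 0)
  if (length(bad)) {
    stop(sprintf("expected count is not positive in cell %d", bad[1]), call. = FALSE)
  }
  sum((observed - expected)^2 / expected)
}

# Bin one weighted feature column against the class label and return the
# contingency chi-square of observed class-conditional counts vs the
# label-marginal expected counts.  Binning rule: columns with at most
# `bins` distinct values keep their values as bin identities (so binary and
# ordinal attributes reproduce the plain contingency table); otherwise
# quartile breaks of the non-negatively shifted weighted values, with a
# median split as fallback when ties collapse the quantile breaks.
binned_chi_square <- function(values, labels, bins = 4L) {
  v <- values - min(values)          # non-negative shift
  if (length(unique(v)) <= bins) {
    bin <- factor(v)
  } else {
    breaks <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                                     names = FALSE, type = 7))
    bin <- cut(v, breaks = breaks, include.lowest = TRUE)
    if (length(unique(bin[!is.na(bin)])) < 2L) bin <- factor(v <= stats::median(v))
  }
  tab <- table(bin, labels)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_square_score(as.vector(tab), as.vector(expected))
}

#' Chi-square association score of a weighted feature selection
#'
#' For each selected column, the column is rescaled by its weight, shifted
#' to be non-negative, discretized into quartile bins, and the contingency
#' chi-square of the binned values against the class label is computed; the
#' score is the sum over selected columns. Higher means the weighted
#' selection carries more label information.
#'
#' @param x Numeric feature matrix or data frame (patients in rows).
#' @param y Class label vector (at least two classes present).
#' @param indices Integer vector of selected column indices.
#' @param weights Numeric weights aligned to `indices`.
#' @param bins Number of quantile bins (default 4).
#' @return Non-negative scalar chi-square score.
#' @export
selection_chi_square <- function(x, y, indices, weights, bins = 4L) {
  x <- as_numeric_matrix(x)
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class: chi-square target is degenerate", call. = FALSE)
  }
  if (any(indices < 1L) || any(indices > ncol(x))) {
    stop("feature index out of range", call. = FALSE)
  }
  total <- 0
  for (j in seq_along(indices)) {
    total <- total + binned_chi_square(weights[j] * x[, indices[j]], y, bins = bins)
  }
  total
}

#' Selection fitness: reciprocal chi-square
#'
#' The feature-selection objective handed to the optimizer:
#' `1 / (chi-square + 1e-12)`, so maximizing label association is
#' equivalent to minimizing fitness. The epsilon guard keeps a zero
#' chi-square finite.
#'
#' @inheritParams selection_chi_square
#' @param feature_genes,weight_genes The raw genome (see
#'   [decode_selection()]).
#' @return Positive scalar fitness; lower is better.
#' @export
selection_fitness <- function(x, y, feature_genes, weight_genes, bins = 4L) {
  dec <- decode_selection(feature_genes, weight_genes, ncol(as_numeric_matrix(x)))
  chi2 <- selection_chi_square(x, y, dec$indices, dec$weights, bins = bins)
  1 / (chi2 + 1e-12)
}

#' Apply optimized weights to selected feature columns
#'
#' Builds the weighted feature matrix: column `j` of the result is
#' `weights[j] * x[, indices[j]]` (elementwise rescaling of each retained
#' column by its tuned weight).
#'
#' @inheritParams selection_chi_square
#' @return A numeric matrix with `length(indices)` columns, carrying the
#'   selected column names.
#' @export
apply_feature_weights <- function(x, indices, weights) {
  x <- as_numeric_matrix(x)
  if (any(indices < 1L) || any(indices > ncol(x))) {
    stop("feature index out of range", call. = FALSE)
  }
  out <- x[, indices, drop = FALSE]
  out <- sweep(out, 2L, weights, `*`)
  colnames(out) <- colnames(x)[indices]
  out
}

#' Weighted optimal feature selection
#'
#' Encodes feature selection as an EAVSRO search over a 2K-gene space: K
#' feature-index genes in `[1, ncol(x)]` and K weight genes in
#' `[0.01, 0.99]`. Fitness is the reciprocal chi-square of the decoded
#' weighted selection ([selection_fitness()]), so the optimizer drives the
#' selection toward label-informative columns and weights.
#'
#' @param x Numeric feature matrix or data frame (patients in rows).
#' @param y Class labels.
#' @param k Selection budget: number of feature/weight gene pairs
#'   (default 10). The decoded selection can be smaller after removing
#'   duplicate indices.
#' @param pop_size,max_iter,seed Optimizer settings (defaults 10 / 50).
#' @param bins Quantile bins for the chi-square discretization.
#' @return An object of class `"weighted_features"`: `indices`, `weights`,
#'   `chi_square`, `transformed` (the weighted feature matrix), the
#'   optimizer `trace`, and the settings used.
#' @examples
#' d <- simulate_heart_data(n_rows = 120, class_counts = c(60, 60), seed = 1)
#' sel <- select_features(d[, -ncol(d)], d$target, k = 3,
#'                        pop_size = 6, max_iter = 5, seed = 1)
#' sel
#' @export
select_features <- function(x, y, k = 10L, pop_size = 10L, max_iter = 50L,
                            seed = 1L, bins = 4L) {
  x <- as_numeric_matrix(x)
  f <- ncol(x)
  if (f < 1L) stop("feature table has no columns", call. = FALSE)
  lower <- c(rep(1, k), rep(0.01, k))
  upper <- c(rep(f, k), rep(0.99, k))
  if (f == 1L) upper[1:k] <- 1 + 1e-9  # degenerate one-column table
  objective <- function(genes) {
    selection_fitness(x, y, genes[seq_len(k)], genes[k + seq_len(k)], bins = bins)
  }
  opt <- sro_optimize(objective, lower, upper, pop_size = pop_size,
                      max_iter = max_iter, seed = seed)
  dec <- decode_selection(opt$best_par[seq_len(k)], opt$best_par[k + seq_len(k)], f)
  chi2 <- selection_chi_square(x, y, dec$indices, dec$weights, bins = bins)
  structure(list(
    indices = dec$indices,
    weights = dec$weights,
    chi_square = chi2,
    transformed = apply_feature_weights(x, dec$indices, dec$weights),
    feature_names = colnames(x)[dec$indices],
    trace = opt$trace,
    k = k, bins = bins, seed = seed,
    pop_size = pop_size, max_iter = max_iter
  ), class = "weighted_features")
}

#' @export
print.weighted_features <- function(x, ...) {
  cat("Weighted optimal feature selection\n")
  nm <- x$feature_names %||% as.character(x$indices)
  cat(sprintf("  %d columns selected (budget %d), chi-square %.4g\n",
              length(x$indices), x$k, x$chi_square))
  for (j in seq_along(x$indices)) {
    cat(sprintf("   [%2d] %-10s weight %.3f\n", x$indices[j], nm[j], x$weights[j]))
  }
  invisible(x)
}

#' Transform new data with a fitted feature selection
#'
#' @param object A `"weighted_features"` fit.
#' @param newdata Feature matrix/data frame with the same columns as the
#'   training table.
#' @param ... Ignored.
#' @return The weighted selected-column matrix for `newdata`.
#' @export
predict.weighted_features <- function(object, newdata, ...) {
  apply_feature_weights(newdata, object$indices, object$weights)
}
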