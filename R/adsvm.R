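#' Adaptive deep-SVM heart disease detector
#'
#' Fits the two-stage hybrid detector: a feed-forward feature extractor (two
#' hidden layers of `hidden_neurons` units, tunable activation, sigmoid
#' output, binary cross-entropy loss, Adam updates, batch size 16) is
#' trained as a standalone classifier, then frozen, and an RBF-kernel SVM
#' decision head is fit on its penultimate-layer activations. The decision
#' head is the classical soft-margin kernel machine whose decision function
#' is a kernel expansion over support vectors plus a bias.
#'
#' The three extractor hyperparameters exposed here are the ones the
#' optimizer tunes in [tune_adsvm()]: learning rate in `[0.01, 0.99]`,
#' per-layer hidden neuron count in `[5, 255]`, and activation index in
#' `[1, 5]` (see [activation_from_index()]). The untuned default learning
#' rate is 0.001.
#'
#' @param x Feature matrix (typically the `transformed` matrix of a
#'   [select_features()] fit).
#' @param y Binary 0/1 labels with at least two examples per class.
#' @param learning_rate Extractor Adam learning rate (default 0.001).
#' @param hidden_neurons Width of each of the two hidden layers.
#' @param activation Activation name or index 1..5.
#' @param epochs Maximum training epochs (default 300).
#' @param batch_size Mini-batch size (default 16).
#' @param patience Early-stopping patience, in epochs, on held-out loss
#'   (default 30).
#' @param cost SVM error penalty parameter `P` (default 1).
#' @param gamma RBF kernel width; default `1 / ncol(deep features)`.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `"adsvm"` with the trained extractor, the SVM
#'   head, hyperparameters and training metadata.
#' @examples
#' d <- simulate_heart_data(n_rows = 80, class_counts = c(40, 40),
#'                          effect_size = 3, seed = 2)
#' x <- as.matrix(d[, 1:4])
#' fit <- adsvm(x, d$target, hidden_neurons = 8, epochs = 30, seed = 2)
#' table(predict(fit, x), d$target)
#' @export
adsvm <- function(x, y, learning_rate = 0.001, hidden_neurons = 64L,
                  activation = "relu", epochs = 300L, batch_size = 16L,
                  patience = 30L, cost = 1, gamma = NULL, seed = 1L) {
  x <- as_numeric_matrix(x)
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("labels must be 0/1", call. = FALSE)
  if (min(table(y)) < 2L) {
    stop("need at least two examples per class", call. = FALSE)
  }
  if (is.numeric(activation) && !is.character(activation)) {
    activation <- activation_from_index(activation)
  }
  hidden_neurons <- as.integer(round(hidden_neurons))
  if (hidden_neurons < 1L) stop("hidden_neurons must be positive", call. = FALSE)

  net <- mlp_train(x, y, hidden = c(hidden_neurons, hidden_neurons),
                   activation = activation, learning_rate = learning_rate,
                   epochs = epochs, batch_size = batch_size,
                   patience = patience, seed = seed)
  feats <- mlp_penultimate(net, x)
  if (any(!is.finite(feats))) {
    stop("extractor produced non-finite deep features", call. = FALSE)
  }
  if (is.null(gamma)) gamma <- 1 / ncol(feats)
  # standardize the deep features inside the head (e1071's own default);
  # constant columns are left unscaled
  scale_cols <- apply(feats, 2L, stats::sd) > 1e-12
  head <- withr::with_seed(child_seed(seed, 77L), {
    e1071::svm(x = feats, y = factor(y, levels = c(0, 1)),
               kernel = "radial", cost = cost, gamma = gamma,
               scale = scale_cols)
  })

  structure(list(
    extractor = net,
    head = head,
    hyperparams = list(learning_rate = learning_rate,
                       hidden_neurons = hidden_neurons,
                       activation = activation),
    cost = cost, gamma = gamma, seed = seed,
    input_dim = ncol(x),
    feature_names = colnames(x)
  ), class = "adsvm")
}

#' Penultimate-layer deep features
#'
#' Runs the frozen extractor of a fitted detector and returns the
#' penultimate-layer activations, one row per input row and one column per
#' hidden neuron — the representation the SVM head decides on.
#'
#' @param object A fitted `"adsvm"` model.
#' @param x Feature matrix with the training input dimension.
#' @return Numeric matrix of deep features.
#' @export
deep_features <- function(object, x) {
  stopifnot(inherits(object, "adsvm"))
  mlp_penultimate(object$extractor, x)
}

#' Predict heart-disease labels
#'
#' @param object A fitted `"adsvm"` model.
#' @param newdata Feature matrix with the training columns.
#' @param type `"class"` for 0/1 labels (1 = disease present) or
#'   `"decision"` for the raw SVM decision values.
#' @param ... Ignored.
#' @return Integer 0/1 vector or numeric decision values.
#' @export
predict.adsvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  feats <- deep_features(object, newdata)
  if (type == "decision") {
    pred <- stats::predict(object$head, feats, decision.values = TRUE)
    return(as.vector(attr(pred, "decision.values")))
  }
  as.integer(as.character(stats::predict(object$head, feats)))
}

#' @export
print.adsvm <- function(x, ...) {
  hp <- x$hyperparams
  cat("Adaptive deep-SVM detector\n")
  cat(sprintf("  extractor: %d -> %d -> %d -> 1 (%s), lr %.4g\n",
              x$input_dim, hp$hidden_neurons, hp$hidden_neurons,
              hp$activation, hp$learning_rate))
  cat(sprintf("  SVM head: RBF kernel, cost %.3g, gamma %.3g, %d support vectors\n",
              x$cost, x$gamma, nrow(x$head$SV)))
  if (!is.null(x$tuning)) {
    cat(sprintf("  tuned by EAVSRO: validation fitness %.4g\n",
                x$tuning$best_fitness))
  }
  invisible(x)
}

#' @export
summary.adsvm <- function(object, ...) {
  print(object)
  if (!is.null(object$validation)) {
    cat("  validation metrics:\n")
    rep <- classification_report(object$validation)
    for (nm in names(rep)) cat(sprintf("    %-9s %.4f\n", nm, rep[nm]))
  }
  invisible(object)
}

#' Detection tuning objective: 1/CSI + FPR
#'
#' The objective minimized when tuning the detector: the reciprocal of the
#' critical success index plus the false positive rate. Its global minimum
#' is 1, attained exactly by a perfect classifier. A zero CSI (no true
#' positives) is guarded with the same epsilon as the selection fitness.
#'
#' @param counts A [confusion_counts()] object from validation predictions.
#' @return Scalar fitness, always `>= 1`; lower is better.
#' @examples
#' detection_fitness(confusion_counts(tp = 50, tn = 50, fp = 0, fn = 0))
#' @export
detection_fitness <- function(counts) {
  check_counts(counts)
  if (counts$tp + counts$fp + counts$fn == 0) {
    stop("detection fitness undefined: TP + FP + FN is zero", call. = FALSE)
  }
  1 / (csi(counts) + 1e-12) + fpr(counts)
}

# Stratified index split used by the tuners: deterministic per seed.
stratified_split <- function(y, train_frac = 0.8, seed = 1L) {
  withr::with_seed(seed, {
    train_idx <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- max(1L, floor(train_frac * length(idx)))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    sort(train_idx)
  })
}

#' Tune the detector with ship-rescue optimization
#'
#' Runs EAVSRO over the 3-gene hyperparameter space — learning rate
#' `[0.01, 0.99]`, hidden neurons `[5, 255]`, activation index `[1, 5]` —
#' minimizing `1/CSI + FPR` ([detection_fitness()]) on a stratified 80/20
#' validation split of the supplied training data. The returned model is
#' retrained on all rows at the best hyperparameters. Candidates whose
#' training fails score worst-possible fitness rather than aborting the
#' search.
#'
#' @inheritParams adsvm
#' @param pop_size,max_iter Optimizer budget (defaults 10 / 50; reduce for
#'   quick runs).
#' @param epochs Extractor epoch budget used both during search and for the
#'   final refit.
#' @return An `"adsvm"` model with an additional `tuning` element holding
#'   the optimizer trace, the selected hyperparameters and the validation
#'   confusion counts of the winning candidate.
#' @export
tune_adsvm <- function(x, y, pop_size = 10L, max_iter = 50L, seed = 1L,
                       epochs = 150L, batch_size = 16L, patience = 30L,
                       cost = 1, gamma = NULL) {
  x <- as_numeric_matrix(x)
  y <- as.integer(y)
  tr_idx <- stratified_split(y, 0.8, seed = child_seed(seed, 1L))
  va_idx <- setdiff(seq_along(y), tr_idx)
  train_seed <- child_seed(seed, 2L)

  decode_hp <- function(genes) {
    list(learning_rate = genes[1],
         hidden_neurons = as.integer(round(clamp_to_bounds(genes[2], 5, 255))),
         activation = activation_from_index(round(clamp_to_bounds(genes[3], 1, 5))))
  }
  objective <- function(genes) {
    hp <- decode_hp(genes)
    fitness <- tryCatch({
      m <- adsvm(x[tr_idx, , drop = FALSE], y[tr_idx],
                 learning_rate = hp$learning_rate,
                 hidden_neurons = hp$hidden_neurons,
                 activation = hp$activation,
                 epochs = epochs, batch_size = batch_size, patience = patience,
                 cost = cost, gamma = gamma, seed = train_seed)
      pred <- predict(m, x[va_idx, , drop = FALSE])
      detection_fitness(tabulate_confusion(y[va_idx], pred))
    }, error = function(e) 1e12)
    fitness
  }

  opt <- sro_optimize(objective, lower = c(0.01, 5, 1), upper = c(0.99, 255, 5),
                      pop_size = pop_size, max_iter = max_iter, seed = seed)
  hp <- decode_hp(opt$best_par)

  model <- adsvm(x, y, learning_rate = hp$learning_rate,
                 hidden_neurons = hp$hidden_neurons, activation = hp$activation,
                 epochs = epochs, batch_size = batch_size, patience = patience,
                 cost = cost, gamma = gamma, seed = train_seed)
  val_model <- adsvm(x[tr_idx, , drop = FALSE], y[tr_idx],
                     learning_rate = hp$learning_rate,
                     hidden_neurons = hp$hidden_neurons, activation = hp$activation,
                     epochs = epochs, batch_size = batch_size, patience = patience,
                     cost = cost, gamma = gamma, seed = train_seed)
  val_counts <- tabulate_confusion(y[va_idx],
                                   predict(val_model, x[va_idx, , drop = FALSE]))
  model$validation <- val_counts
  model$tuning <- list(best_fitness = opt$best_fitness,
                       best_genes = opt$best_par,
                       hyperparams = hp,
                       trace = opt$trace,
                       seed = seed)
  model
}
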