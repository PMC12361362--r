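#' Read a clinical CSV table
#'
#' Loads a patient table for the pipeline: numeric columns are kept as-is,
#' missing numeric cells are imputed with the column median (the count of
#' imputations is reported as a message), and categorical columns are
#' integer-encoded with the level mapping stored as an attribute.
#'
#' @param path Path to a CSV file with a header row.
#' @param label_col Name of the label column that must be present
#'   (default `"target"`).
#' @return A data frame with attributes `imputed` (named count of imputed
#'   cells per column) and `encodings` (level mappings of encoded columns).
#' @export
read_heart_csv <- function(path, label_col = "target") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("input CSV is empty", call. = FALSE)
  if (!label_col %in% names(data)) {
    stop(sprintf("label column '%s' not found in %s", label_col, path), call. = FALSE)
  }
  imputed <- integer(0)
  encodings <- list()
  for (nm in names(data)) {
    col <- data[[nm]]
    if (is.character(col) || is.factor(col)) {
      lev <- sort(unique(as.character(col)))
      encodings[[nm]] <- stats::setNames(seq_along(lev), lev)
      data[[nm]] <- as.integer(encodings[[nm]][as.character(col)])
    }
    n_missing <- sum(is.na(data[[nm]]))
    if (n_missing > 0L) {
      data[[nm]][is.na(data[[nm]])] <- stats::median(data[[nm]], na.rm = TRUE)
      imputed[nm] <- n_missing
    }
  }
  if (length(imputed)) {
    message(sprintf("imputed %d missing cells with column medians (%s)",
                    sum(imputed),
                    paste(names(imputed), imputed, sep = ": ", collapse = ", ")))
  }
  attr(data, "imputed") <- imputed
  attr(data, "encodings") <- encodings
  data
}

#' Run the full detection + AF-rate pipeline
#'
#' Executes the staged analysis on one table: stratified 80/20 split,
#' EAVSRO-weighted feature selection on the training partition, detector
#' tuning and test-set evaluation, and — only for test patients the
#' detector labels as diseased — AF-rate regression with the tuned capsule
#' network, mirroring the clinical flow in which the AF rate is determined
#' once heart disease is detected. When no test patient is predicted
#' positive the AF stage is skipped with a notice.
#'
#' @param data A patient data frame (e.g. from [simulate_heart_data()] or
#'   [read_heart_csv()]). Mutually exclusive with `path`.
#' @param path CSV path, read with [read_heart_csv()].
#' @param label_col Binary 0/1 label column name (default `"target"`).
#' @param af_col AF-rate column name, or `NULL` to skip the AF stage
#'   (default `"af_rate"`, skipped silently when absent).
#' @param k Feature-selection budget (default 10).
#' @param pop_size,max_iter Optimizer budget shared by all three EAVSRO
#'   stages (defaults 10 / 50; reduce for quick runs).
#' @param seed Master seed; the entire run is reproducible given the seed.
#' @param extractor_epochs,capsnet_epochs Per-stage training budgets.
#' @param percent Report `[0, 1]` metrics as percentages.
#' @param out_dir If non-`NULL`, write `report.json`, the resolved
#'   configuration and the optimizer convergence traces (CSV) there.
#' @return An object of class `"heart_pipeline"`: a list with the split
#'   bookkeeping, the selection, both tuned models, test-set
#'   classification metrics, and (when run) AF regression metrics.
#' @export
run_pipeline <- function(data = NULL, path = NULL, label_col = "target",
                         af_col = "af_rate", k = 10L, pop_size = 10L,
                         max_iter = 50L, seed = 1L,
                         extractor_epochs = 100L, capsnet_epochs = 40L,
                         percent = FALSE, out_dir = NULL) {
  if (is.null(data) == is.null(path)) {
    stop("supply exactly one of `data` or `path`", call. = FALSE)
  }
  if (!is.null(path)) data <- read_heart_csv(path, label_col = label_col)
  has_af <- !is.null(af_col) && af_col %in% names(data)

  config <- list(label_col = label_col, af_col = if (has_af) af_col,
                 k = k, pop_size = pop_size, max_iter = max_iter, seed = seed,
                 extractor_epochs = extractor_epochs,
                 capsnet_epochs = capsnet_epochs, percent = percent)

  drop_cols <- c(label_col, if (has_af) af_col, "severity", "site")
  feature_cols <- setdiff(names(data), drop_cols)
  sp <- split_train_test(data, seed = seed, label_col = label_col)
  x_train <- as_numeric_matrix(sp$train[, feature_cols, drop = FALSE])
  x_test <- as_numeric_matrix(sp$test[, feature_cols, drop = FALSE])
  y_train <- as.integer(sp$train[[label_col]])
  y_test <- as.integer(sp$test[[label_col]])

  selection <- select_features(x_train, y_train, k = k, pop_size = pop_size,
                               max_iter = max_iter, seed = child_seed(seed, 21L))
  ft_train <- selection$transformed
  ft_test <- predict(selection, x_test)

  # the capsule stem needs at least 7 columns; pad a narrow selection with
  # zero columns so the AF stage stays runnable
  pad_to_width <- function(m, width = 7L) {
    if (ncol(m) >= width) return(m)
    message(sprintf("selection has %d columns; zero-padding to %d for the AF stage",
                    ncol(m), width))
    cbind(m, matrix(0, nrow(m), width - ncol(m)))
  }

  detector <- tune_adsvm(ft_train, y_train, pop_size = pop_size,
                         max_iter = max_iter, seed = child_seed(seed, 22L),
                         epochs = extractor_epochs)
  pred_test <- predict(detector, ft_test)
  counts <- tabulate_confusion(y_test, pred_test)
  detection <- classification_report(counts, percent = percent)

  af <- NULL
  if (has_af) {
    pos_test <- which(pred_test == 1L)
    if (length(pos_test) == 0L) {
      message("no test patient predicted positive: AF stage skipped")
    } else {
      af_model <- tune_amccnet(pad_to_width(ft_train[y_train == 1L, , drop = FALSE]),
                               sp$train[[af_col]][y_train == 1L],
                               pop_size = pop_size, max_iter = max_iter,
                               seed = child_seed(seed, 23L),
                               epochs = capsnet_epochs)
      af_pred <- predict(af_model, pad_to_width(ft_test[pos_test, , drop = FALSE]))
      af_actual <- sp$test[[af_col]][pos_test]
      af <- list(model = af_model,
                 n_predicted_positive = length(pos_test),
                 metrics = regression_report(af_actual, af_pred,
                                             percent = percent),
                 predictions = af_pred, actual = af_actual)
    }
  }

  report <- structure(list(
    config = config,
    split = list(n = nrow(data), n_train = nrow(sp$train),
                 n_test = nrow(sp$test)),
    selection = selection,
    detector = detector,
    confusion = counts,
    detection_metrics = detection,
    af = af,
    seed = seed
  ), class = "heart_pipeline")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    config = report$config,
    split = report$split,
    selection = list(indices = report$selection$indices,
                     weights = report$selection$weights,
                     chi_square = report$selection$chi_square),
    detector_hyperparams = report$detector$tuning$hyperparams,
    confusion = unclass(report$confusion),
    detection_metrics = as.list(report$detection_metrics),
    af_metrics = if (!is.null(report$af)) as.list(report$af$metrics),
    af_hyperparams = if (!is.null(report$af)) report$af$model$tuning$hyperparams,
    seed = report$seed
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  utils::write.csv(data.frame(iteration = seq_along(report$selection$trace),
                              best_fitness = report$selection$trace),
                   file.path(out_dir, "selection_trace.csv"), row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(report$detector$tuning$trace),
                              best_fitness = report$detector$tuning$trace),
                   file.path(out_dir, "detector_trace.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.heart_pipeline <- function(x, ...) {
  cat("Heart-disease detection pipeline\n")
  cat(sprintf("  rows: %d (train %d / test %d), seed %d\n",
              x$split$n, x$split$n_train, x$split$n_test, x$seed))
  cat(sprintf("  selected features: %s\n",
              paste(x$selection$feature_names %||% x$selection$indices,
                    collapse = ", ")))
  cat("  test-set detection metrics:\n")
  for (nm in names(x$detection_metrics)) {
    cat(sprintf("    %-9s %.4f\n", nm, x$detection_metrics[nm]))
  }
  if (!is.null(x$af)) {
    cat(sprintf("  AF stage (%d predicted-positive patients):\n",
                x$af$n_predicted_positive))
    for (nm in names(x$af$metrics)) {
      cat(sprintf("    %-9s %.4f\n", nm, x$af$metrics[nm]))
    }
  }
  invisible(x)
}
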