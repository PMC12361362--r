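#' Simulate tabular clinical heart-disease data
#'
#' Generates a synthetic patient table with the statistical shape the
#' pipeline assumes: a handful of informative columns whose class-conditional
#' means are separated by `effect_size`, the remaining columns pure
#' standard-normal noise, exact (not expected) class counts, and clinical
#' attribute names. The defaults emulate the 1026-patient binary cohort
#' (500 absence / 526 presence, 14 attributes); `dataset = "severity"`
#' instead emulates the 920-patient multi-site cohort (sites of 303, 294,
#' 123 and 200 patients) with a 5-level severity label, which the detection
#' pipeline collapses to binary (0 vs 1-4).
#'
#' The table is a declared statistical stand-in: it reproduces planted
#' feature/label association and cohort bookkeeping, not physiological
#' covariance between attributes.
#'
#' @param n_rows Number of patients (default 1026; ignored with a warning in
#'   severity mode, which is fixed at 920).
#' @param n_features Number of attribute columns (default 14).
#' @param n_informative Number of label-informative columns, planted as the
#'   first columns (default 2).
#' @param class_counts Exact label counts `c(absent, present)` (default
#'   `c(500, 526)`).
#' @param effect_size Class-mean separation of informative columns
#'   (default 1.5).
#' @param noise_sd Within-class standard deviation of informative columns
#'   (default 1).
#' @param seed Integer seed; the table is identical for identical seeds.
#' @param dataset `"binary"` (default) or `"severity"`.
#' @return A data frame of `n_features` numeric columns plus an integer
#'   `target` column (and `site` and `severity` columns in severity mode),
#'   with attributes `informative` (planted column indices) and `sim_spec`
#'   (the generating settings).
#' @examples
#' d <- simulate_heart_data(seed = 1)
#' table(d$target)
#' @export
simulate_heart_data <- function(n_rows = 1026L, n_features = 14L,
                                n_informative = 2L,
                                class_counts = c(500L, 526L),
                                effect_size = 1.5, noise_sd = 1,
                                seed = 1L,
                                dataset = c("binary", "severity")) {
  dataset <- match.arg(dataset)
  if (n_informative > n_features) {
    stop("n_informative cannot exceed n_features", call. = FALSE)
  }

  site_sizes <- c(Cleveland = 303L, Hungarian = 294L, Switzerland = 123L,
                  `VA Long Beach` = 200L)
  if (dataset == "severity") {
    n_rows <- sum(site_sizes)   # 920
  } else {
    if (sum(class_counts) != n_rows) {
      stop("class_counts must sum to n_rows", call. = FALSE)
    }
  }

  clinical_names <- c("age", "sex", "cp", "trestbps", "chol", "fbs",
                      "restecg", "thalach", "exang", "oldpeak", "slope",
                      "ca", "thal")
  col_names <- if (n_features <= length(clinical_names)) {
    clinical_names[seq_len(n_features)]
  } else {
    c(clinical_names, paste0("attr", seq_len(n_features - length(clinical_names))))
  }

  withr::with_seed(seed, {
    if (dataset == "binary") {
      y <- sample(rep(c(0L, 1L), times = class_counts))
      severity <- y
      site <- NULL
    } else {
      site <- rep(names(site_sizes), times = site_sizes)
      # severity 0-4; graded class mix, heavier on the healthy end
      severity <- sample(0:4, n_rows, replace = TRUE,
                         prob = c(0.44, 0.24, 0.14, 0.11, 0.07))
      y <- as.integer(severity >= 1L)
    }
    x <- matrix(stats::rnorm(n_rows * n_features), n_rows, n_features)
    if (n_informative > 0L) {
      shift <- if (dataset == "binary") y * effect_size else
        severity / 4 * effect_size
      for (j in seq_len(n_informative)) {
        x[, j] <- stats::rnorm(n_rows, mean = shift, sd = noise_sd)
      }
    }
    colnames(x) <- col_names
    out <- as.data.frame(x)
    out$target <- y
    if (dataset == "severity") {
      out$severity <- as.integer(severity)
      out$site <- site
    }
    attr(out, "informative") <- seq_len(n_informative)
    attr(out, "sim_spec") <- list(n_rows = n_rows, n_features = n_features,
                                  n_informative = n_informative,
                                  class_counts = class_counts,
                                  effect_size = effect_size,
                                  noise_sd = noise_sd, seed = seed,
                                  dataset = dataset,
                                  site_sizes = if (dataset == "severity") site_sizes)
    out
  })
}

#' Attach a synthetic AF-rate target
#'
#' Adds a continuous atrial-fibrillation rate column with a documented
#' closed-form generative model so recovery tests know the ground truth:
#' with `z1`, `z2` the standardized first two informative columns,
#'
#' `af = plogis(0.8 * z1 + 0.6 * z2^2 - 0.5) + N(0, af_noise_sd)`,
#'
#' clipped to `[0, 1]`. This recipe is a declared fiction: no public
#' heart-disease table carries an AF-rate field, so the generator defines
#' one whose functional form is exported for test oracles.
#'
#' @param data A table from [simulate_heart_data()] (needs at least 2
#'   informative columns).
#' @param af_noise_sd Gaussian noise level on the rate (default 0.05).
#' @param seed Integer seed for the noise.
#' @return `data` with an added `af_rate` column and an `af_truth`
#'   attribute holding the noiseless rates and the generative coefficients.
#' @export
attach_af_rate <- function(data, af_noise_sd = 0.05, seed = 1L) {
  info <- attr(data, "informative")
  if (is.null(info) || length(info) < 2L) {
    stop("need at least 2 informative columns to define the AF rate", call. = FALSE)
  }
  z1 <- as.vector(scale(data[[info[1]]]))
  z2 <- as.vector(scale(data[[info[2]]]))
  truth <- stats::plogis(0.8 * z1 + 0.6 * z2^2 - 0.5)
  af <- withr::with_seed(seed, truth + stats::rnorm(length(truth), sd = af_noise_sd))
  data$af_rate <- pmin(pmax(af, 0), 1)
  attr(data, "af_truth") <- list(noiseless = truth, af_noise_sd = af_noise_sd,
                                 coefficients = c(z1 = 0.8, z2_sq = 0.6,
                                                  intercept = -0.5))
  data
}

#' Stratified 80/20 train/test split
#'
#' Splits a patient table into a training partition of exactly
#' `ceiling(0.8 * n)` rows and a test partition of the remainder (so 1026
#' rows give 821/205 and 920 rows give 736/184), stratified by the label.
#' Per-class training counts are apportioned by largest remainder so the
#' total is exact. Classes with a single row trigger a warning and an
#' unstratified fallback.
#'
#' @param data A data frame with a label column.
#' @param seed Integer seed; the partition is deterministic per seed.
#' @param label_col Label column name (default `"target"`).
#' @return A list with data frames `train` and `test`; the two are
#'   disjoint and exhaust the input rows.
#' @examples
#' d <- simulate_heart_data(seed = 1)
#' sp <- split_train_test(d, seed = 1)
#' c(nrow(sp$train), nrow(sp$test))  # 821 205
#' @export
split_train_test <- function(data, seed = 1L, label_col = "target") {
  n <- nrow(data)
  if (n < 5L) stop("need at least 5 rows to split", call. = FALSE)
  y <- data[[label_col]]
  if (is.null(y)) stop(sprintf("label column '%s' not found", label_col), call. = FALSE)
  n_train <- as.integer(ceiling(0.8 * n))

  withr::with_seed(seed, {
    if (min(table(y)) < 2L) {
      warning("a class has a single row; falling back to an unstratified split")
      train_idx <- sample(n, n_train)
    } else {
      classes <- unique(y)
      quota_raw <- vapply(classes, function(cl) 0.8 * sum(y == cl), numeric(1))
      quota <- floor(quota_raw)
      short <- n_train - sum(quota)
      if (short > 0) {
        order_frac <- order(quota_raw - quota, decreasing = TRUE)
        quota[order_frac[seq_len(short)]] <- quota[order_frac[seq_len(short)]] + 1
      }
      train_idx <- unlist(lapply(seq_along(classes), function(i) {
        idx <- which(y == classes[i])
        sample(idx, quota[i])
      }))
    }
    train_idx <- sort(train_idx)
    list(train = data[train_idx, , drop = FALSE],
         test = data[setdiff(seq_len(n), train_idx), , drop = FALSE])
  })
}
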