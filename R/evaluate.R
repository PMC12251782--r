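# Dataset splitting, RMSE / R^2 / CORR metrics, and the multi-model
# benchmark harness.

#' Random train/test split
#'
#' Seeded uniform random partition; the training set holds
#' `floor(ratio * n)` samples and the test set the remainder.
#'
#' @param n number of samples (or a list of samples, in which case the
#'   samples themselves are returned split).
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed RNG seed.
#' @param chronological if `TRUE`, the first `floor(ratio n)` samples form
#'   the training set instead of a random subset (for leakage-sensitive
#'   sliding-window experiments).
#' @return list with `train` and `test` (integer indices, or sample lists).
#' @export
split_dataset <- function(n, ratio = 0.8, seed = 1, chronological = FALSE) {
  samples <- NULL
  if (is.list(n)) {
    samples <- n
    n <- length(samples)
  }
  stopifnot(ratio > 0, ratio < 1)
  if (n < 2) stop("need at least 2 samples to split")
  n_train <- floor(ratio * n)
  if (chronological) {
    tr <- seq_len(n_train)
  } else {
    set.seed(seed)
    tr <- sort(sample.int(n, n_train))
  }
  te <- setdiff(seq_len(n), tr)
  if (is.null(samples)) list(train = tr, test = te)
  else list(train = samples[tr], test = samples[te])
}

#' RMSE, R-squared and Pearson correlation of predictions
#'
#' Metrics are computed per gas (over the rows of each column) and pooled
#' over all (sample, gas) pairs. `RMSE = sqrt(mean((yhat - y)^2))`;
#' `R2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)`; `CORR` is the
#' Pearson correlation of y and yhat. For a constant truth vector R2/CORR
#' are undefined and returned as `NA` (RMSE is still returned).
#'
#' @param y_true matrix (or vector) of true concentrations (ppm).
#' @param y_pred matrix of predictions, same shape.
#' @return object of class `enose_metrics`: list with `pooled` (named
#'   vector rmse/r2/corr), `per_gas` (8 x 3 matrix), `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch")
  if (length(y_true) < 2) stop("need at least 2 predictions")
  one <- function(y, p) {
    rmse <- sqrt(mean((p - y)^2))
    if (sd(y) == 0) return(c(rmse = rmse, r2 = NA_real_, corr = NA_real_))
    r2 <- 1 - sum((p - y)^2) / sum((mean(y) - y)^2)
    corr <- if (sd(p) == 0) NA_real_ else cor(y, p)
    c(rmse = rmse, r2 = r2, corr = corr)
  }
  per_gas <- t(apply(cbind(seq_len(ncol(y_true))), 1, function(j) {
    one(y_true[, j], y_pred[, j])
  }))
  rownames(per_gas) <- colnames(y_true) %||% paste0("y", seq_len(ncol(y_true)))
  colnames(per_gas) <- c("rmse", "r2", "corr")
  pooled <- one(as.vector(y_true), as.vector(y_pred))
  structure(list(pooled = pooled, per_gas = per_gas, n = nrow(y_true)),
            class = "enose_metrics")
}

#' @export
print.enose_metrics <- function(x, ...) {
  cat(sprintf("<enose_metrics> n=%d  RMSE %.3f  R2 %.3f  CORR %.3f\n",
              x$n, x$pooled["rmse"], x$pooled["r2"], x$pooled["corr"]))
  invisible(x)
}

#' Benchmark a roster of models on a common split
#'
#' Trains each requested model on the shared training set and evaluates on
#' train and test, one row per model x seed x split (the structure of the
#' headline result tables). Deep models consume windows; baseline names
#' (KNN/SVM/RF/XGBoost/MLP) consume the feature tables, which must then be
#' supplied.
#'
#' @param models character vector of deep and/or baseline model names.
#' @param data list with `train` and `test` window lists, and optionally
#'   `train_features` / `test_features` for baselines.
#' @param seeds integer vector of training seeds (one run per seed).
#' @param channels input channels for the deep models.
#' @param ... config overrides shared by all deep models (fairness rule).
#' @param verbose print progress.
#' @return data.frame with columns model, seed, split, rmse, r2, corr.
#' @export
run_benchmark <- function(models, data, seeds = 1, channels = NULL,
                          verbose = FALSE, ...) {
  rows <- list()
  for (mname in models) {
    is_deep <- !toupper(mname) %in% toupper(BASELINE_MODELS)
    for (sd_i in seeds) {
      if (is_deep) {
        fit <- fit_enose(data$train, model = mname, channels = channels,
                         seed = sd_i, ...)
        pr_tr <- predict(fit, data$train)
        pr_te <- predict(fit, data$test)
        y_tr <- windows_to_arrays(data$train, channels)$y
        y_te <- windows_to_arrays(data$test, channels)$y
      } else {
        if (is.null(data$train_features)) {
          stop("baseline models need train_features/test_features")
        }
        fit <- fit_baseline(mname, data$train_features)
        pr_tr <- predict(fit, data$train_features)
        pr_te <- predict(fit, data$test_features)
        y_tr <- .features_xy(data$train_features)$y
        y_te <- .features_xy(data$test_features)$y
      }
      m_tr <- compute_metrics(y_tr, pr_tr)$pooled
      m_te <- compute_metrics(y_te, pr_te)$pooled
      rows[[length(rows) + 1]] <- data.frame(
        model = mname, seed = sd_i,
        split = c("train", "test"),
        rmse = c(m_tr["rmse"], m_te["rmse"]),
        r2 = c(m_tr["r2"], m_te["r2"]),
        corr = c(m_tr["corr"], m_te["corr"]),
        row.names = NULL)
      if (verbose) {
        message(sprintf("%-16s seed %d  test RMSE %.3f  R2 %.3f",
                        mname, sd_i, m_te["rmse"], m_te["r2"]))
      }
    }
  }
  do.call(rbind, rows)
}
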