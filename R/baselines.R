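# Classical baseline regressors on the 9-features-per-channel table:
# KNN, SVM, RF, XGBoost, MLP, with the benchmark's fixed hyperparameters.

BASELINE_MODELS <- c("KNN", "SVM", "RF", "XGBoost", "MLP")

#' Baseline configuration
#'
#' Defaults are the benchmark's fixed optima: KNN k = 4 with inverse-distance
#' weights; SVM with an RBF kernel and penalty C = 50; random forest with
#' 700 trees, maximum depth 9, seed 42; XGBoost with 850 learners, learning
#' rate 0.025, depth 4 and complexity penalty 0.026; MLP with hidden layers
#' 300/150, Adam at learning rate 4e-4, 100 iterations.
#'
#' @param name one of `r paste(BASELINE_MODELS, collapse = ", ")`.
#' @param ... hyperparameter overrides (see defaults in the source).
#' @return list of class `enose_baseline_config`.
#' @export
baseline_config <- function(name, ...) {
  name <- BASELINE_MODELS[match(toupper(name), toupper(BASELINE_MODELS))]
  if (is.na(name)) stop("unknown baseline name")
  defaults <- switch(name,
    KNN = list(k = 4, weights = "distance"),
    SVM = list(kernel = "radial", cost = 50),
    RF = list(num_trees = 700, max_depth = 9, seed = 42),
    XGBoost = list(nrounds = 850, eta = 0.025, max_depth = 4, gamma = 0.026),
    MLP = list(hidden = c(300, 150), lr = 4e-4, epochs = 100, batch = 32,
               seed = 1)
  )
  structure(utils::modifyList(c(list(name = name), defaults), list(...)),
            class = "enose_baseline_config")
}

#' Fit a classical baseline on a feature table
#'
#' Single-output learners are wrapped per gas (8 independent fits). Features
#' are standardized internally for KNN, SVM and MLP.
#'
#' @param config an `enose_baseline_config` (or a model name).
#' @param features an `enose_features` table.
#' @return object of class `enose_baseline` supporting [predict()] on a new
#'   feature table (or feature matrix).
#' @export
fit_baseline <- function(config, features) {
  if (is.character(config)) config <- baseline_config(config)
  stopifnot(inherits(config, "enose_baseline_config"))
  xy <- .features_xy(features)
  X <- xy$x; Y <- xy$y
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  fitobj <- switch(config$name,
    KNN = list(X = Xs, Y = Y, k = config$k, weights = config$weights),
    SVM = lapply(seq_len(ncol(Y)), function(j) {
      e1071::svm(Xs, Y[, j], kernel = config$kernel, cost = config$cost,
                 type = "eps-regression", scale = FALSE)
    }),
    RF = lapply(seq_len(ncol(Y)), function(j) {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(Xs)))
      df$.y <- Y[, j]
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = config$num_trees,
                     max.depth = config$max_depth,
                     seed = config$seed, num.threads = 1)
    }),
    XGBoost = lapply(seq_len(ncol(Y)), function(j) {
      xgboost::xgboost(Xs, Y[, j], nrounds = config$nrounds,
                       learning_rate = config$eta,
                       max_depth = config$max_depth,
                       min_split_loss = config$gamma,
                       nthreads = 1, verbosity = 0)
    }),
    MLP = .fit_mlp(Xs, Y, config)
  )
  structure(list(config = config, fit = fitobj, center = ctr, scale = scl,
                 n_features = ncol(X)),
            class = "enose_baseline")
}

# MLP on flat features using the package's own engine
.fit_mlp <- function(Xs, Y, config) {
  set.seed(config$seed)
  hid <- config$hidden
  layers <- list(nn_dense(ncol(Xs), hid[1], act = "relu"))
  for (i in seq_along(hid)[-1]) {
    layers <- c(layers, list(nn_dense(hid[i - 1], hid[i], act = "relu")))
  }
  layers <- c(layers, list(nn_dense(hid[length(hid)], ncol(Y))))
  sy <- fit_scaler(Y)
  Ys <- apply_scaler(sy, Y)
  N <- nrow(Xs)
  t_step <- 0L
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(N)
    for (b0 in seq(1, N, by = config$batch)) {
      bi <- idx[b0:min(b0 + config$batch - 1, N)]
      xb <- Xs[bi, , drop = FALSE]
      pred <- .seq_fwd(layers, xb)
      err <- pred - Ys[bi, , drop = FALSE]
      .seq_bwd(layers, 2 * err / length(err))
      t_step <- t_step + 1L
      .adam_step(layers, config$lr, t_step)
    }
  }
  list(layers = layers, scaler_y = sy)
}

#' @export
predict.enose_baseline <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "enose_features")) .features_xy(newdata)$x
       else as.matrix(newdata)
  stopifnot(ncol(X) == object$n_features)
  Xs <- scale(X, center = object$center, scale = object$scale)
  cfg <- object$config
  out <- switch(cfg$name,
    KNN = .predict_knn(object$fit, Xs),
    SVM = vapply(object$fit, function(f) as.numeric(predict(f, Xs)),
                 numeric(nrow(Xs))),
    RF = vapply(object$fit, function(f) {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(Xs)))
      predict(f, data = df, num.threads = 1)$predictions
    }, numeric(nrow(Xs))),
    XGBoost = vapply(object$fit, function(f) {
      as.numeric(predict(f, Xs))
    }, numeric(nrow(Xs))),
    MLP = invert_scaler(object$fit$scaler_y,
                        .seq_fwd(object$fit$layers, Xs))
  )
  out <- matrix(out, nrow = nrow(Xs))
  colnames(out) <- GAS_NAMES
  out
}

# distance-weighted k-nearest-neighbour regression; an exact training-point
# query returns that point's target (infinite weight convention)
.predict_knn <- function(fit, Xs) {
  n <- nrow(fit$X)
  k <- min(fit$k, n)
  out <- matrix(0, nrow(Xs), ncol(fit$Y))
  for (i in seq_len(nrow(Xs))) {
    d2 <- colSums((t(fit$X) - Xs[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    dd <- sqrt(d2[nn])
    if (fit$weights == "distance") {
      if (any(dd < 1e-12)) {
        w <- as.numeric(dd < 1e-12)
      } else {
        w <- 1 / dd
      }
    } else {
      w <- rep(1, k)
    }
    w <- w / sum(w)
    out[i, ] <- colSums(fit$Y[nn, , drop = FALSE] * w)
  }
  out
}

#' @export
print.enose_baseline <- function(x, ...) {
  cat("<enose_baseline> ", x$config$name, " on ", x$n_features,
      " features\n", sep = "")
  invisible(x)
}
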