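# Ensemble feature ranking (Pearson / binned-MI / RF / SVM-RFE), mean-rank
# aggregation and sensor-channel selection.

# average-rank helper: smaller score = better feature -> rank 1
.avg_rank <- function(score_worst_high) {
  rank(score_worst_high, ties.method = "average")
}

# binned mutual information between x and y (equal-frequency bins).
# Stands in for the maximal information coefficient: a plain nonparametric
# dependence score on the same 0..log scale.
.binned_mi <- function(x, y, bins = 8) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  qx <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  qy <- unique(stats::quantile(y, probs = seq(0, 1, length.out = bins + 1)))
  if (length(qx) < 3 || length(qy) < 3) return(0)
  bx <- cut(x, qx, include.lowest = TRUE)
  by <- cut(y, qy, include.lowest = TRUE)
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  ok <- p > 0
  sum(p[ok] * log(p[ok] / outer(px, py)[ok]))
}

#' Rank feature columns by a single selection method
#'
#' Smaller rank = more informative feature; ties get the average rank.
#' Multi-target (8-gas) aggregation: `pearson` and `mic` score each feature
#' by its maximum absolute association over the 8 targets (`aggregate =
#' "mean"` available); `rf` averages impurity importance over per-target
#' random forests; `svmrfe` runs recursive feature elimination with a linear
#' support-vector regressor per target (removing 10% of the surviving
#' features per iteration) and averages the per-target elimination ranks.
#' Constant feature columns receive the worst score rather than NA.
#'
#' @param method one of `"pearson"`, `"mic"`, `"rf"`, `"svmrfe"`.
#' @param features an `enose_features` table (>= 20 samples).
#' @param aggregate `"max"` (default) or `"mean"` over the 8 targets
#'   (pearson/mic only).
#' @param rf_trees trees per per-target forest (default 100).
#' @param seed RNG seed for the stochastic rankers.
#' @return numeric rank vector named by feature column (1 = best).
#' @export
rank_features <- function(method = c("pearson", "mic", "rf", "svmrfe"),
                          features, aggregate = c("max", "mean"),
                          rf_trees = 100, seed = 1) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  xy <- .features_xy(features)
  X <- xy$x; Y <- xy$y
  if (nrow(X) < 20) stop("need at least 20 samples to rank features")
  m <- ncol(X)
  agg <- if (aggregate == "max") function(v) max(v) else function(v) mean(v)

  score <- switch(method,
    pearson = apply(X, 2, function(x) {
      if (sd(x) == 0) return(0)
      agg(abs(apply(Y, 2, function(y) {
        if (sd(y) == 0) 0 else cor(x, y)
      })))
    }),
    mic = apply(X, 2, function(x) {
      agg(apply(Y, 2, function(y) .binned_mi(x, y)))
    }),
    rf = {
      set.seed(seed)
      imp <- matrix(0, m, ncol(Y))
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(m))
      for (j in seq_len(ncol(Y))) {
        df$.y <- Y[, j]
        fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                              num.trees = rf_trees, importance = "impurity",
                              seed = seed + j, num.threads = 1)
        imp[, j] <- fit$variable.importance[paste0("f", seq_len(m))]
      }
      rowMeans(imp)
    },
    svmrfe = {
      elim_ranks <- matrix(0, m, ncol(Y))
      for (j in seq_len(ncol(Y))) {
        elim_ranks[, j] <- .svmrfe_rank(X, Y[, j])
      }
      # smaller elimination rank = better; convert to a score (higher better)
      -rowMeans(elim_ranks)
    }
  )
  r <- .avg_rank(-score)
  names(r) <- colnames(X)
  r
}

# SVM-RFE for one target: returns elimination rank per feature (1 = kept
# longest = best). Removes 10% (at least 1) of surviving features per
# iteration, scored by squared linear-SVR weights.
.svmrfe_rank <- function(X, y, frac = 0.1) {
  m <- ncol(X)
  surviving <- seq_len(m)
  out <- numeric(m)
  next_rank <- m
  sdx <- apply(X, 2, sd)
  # constant columns are eliminated first (worst ranks)
  const <- which(sdx == 0)
  if (length(const)) {
    out[const] <- seq(m, by = -1, length.out = length(const))
    next_rank <- m - length(const)
    surviving <- setdiff(surviving, const)
  }
  Xs <- scale(X[, , drop = FALSE])
  Xs[, sdx == 0] <- 0
  if (sd(y) == 0) {
    out[surviving] <- seq(next_rank, by = -1, length.out = length(surviving))
    return(out)
  }
  while (length(surviving) > 1) {
    fit <- e1071::svm(Xs[, surviving, drop = FALSE], y, kernel = "linear",
                      type = "eps-regression", scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)  # 1 x k weight vector
    crit <- as.numeric(w)^2
    n_drop <- max(1L, floor(frac * length(surviving)))
    drop_idx <- order(crit)[seq_len(n_drop)]
    dropped <- surviving[drop_idx]
    out[dropped] <- seq(next_rank, by = -1, length.out = n_drop)
    next_rank <- next_rank - n_drop
    surviving <- surviving[-drop_idx]
  }
  out[surviving] <- next_rank
  out
}

#' Ensemble (mean) rank over selection methods
#'
#' @param per_method matrix with one row per method, one column per feature
#'   (or a list of equal-length rank vectors).
#' @return numeric vector of mean ranks per feature.
#' @export
ensemble_rank <- function(per_method) {
  if (is.list(per_method)) {
    len <- lengths(per_method)
    if (length(unique(len)) != 1) stop("ragged rank vectors")
    per_method <- do.call(rbind, per_method)
  }
  colMeans(per_method)
}

#' Sensor-channel ranks from feature ranks
#'
#' Each sensor's rank is the mean of the ensemble ranks of its features.
#'
#' @param ensemble named numeric vector of per-feature ensemble ranks.
#' @param channel_map named character vector mapping feature -> sensor id
#'   (as produced by [extract_features()]).
#' @return named numeric vector of sensor ranks (smaller = better).
#' @export
sensor_rank <- function(ensemble, channel_map) {
  unmapped <- setdiff(names(ensemble), names(channel_map))
  if (length(unmapped)) stop("unmapped feature(s): ",
                             paste(head(unmapped, 3), collapse = ", "))
  tap <- tapply(ensemble, channel_map[names(ensemble)], mean)
  setNames(as.numeric(tap), names(tap))
}

#' Select model input channels from sensor ranks
#'
#' Returns the `k` best-ranked gas channels (ties broken by channel id),
#' in rank order, with the `always_include` environment channels appended.
#'
#' @param sensor_ranks named numeric vector from [sensor_rank()].
#' @param k number of gas channels to keep (1..S).
#' @param always_include channels appended unconditionally (default S22/S23).
#' @return ordered character vector of channel ids.
#' @export
select_channels <- function(sensor_ranks, k = 16, always_include = c("S22", "S23")) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, length(sensor_ranks))
  ord <- order(sensor_ranks, names(sensor_ranks))
  c(names(sensor_ranks)[ord][seq_len(k)], always_include)
}

#' Full ensemble ranking of a feature table
#'
#' Runs all four rankers, aggregates by mean rank, and derives sensor ranks.
#'
#' @param features an `enose_features` table.
#' @param methods rankers to use.
#' @param seed RNG seed.
#' @param ... passed to [rank_features()].
#' @return object of class `enose_ranks`: list with `per_method` (N x m
#'   matrix), `ensemble`, `sensor`, `channel_map`.
#' @export
rank_ensemble <- function(features,
                          methods = c("pearson", "mic", "rf", "svmrfe"),
                          seed = 1, ...) {
  per <- lapply(methods, function(mth) rank_features(mth, features,
                                                     seed = seed, ...))
  per_method <- do.call(rbind, per)
  rownames(per_method) <- methods
  ens <- ensemble_rank(per_method)
  cmap <- attr(features, "channel_map")
  structure(list(per_method = per_method, ensemble = ens,
                 sensor = sensor_rank(ens, cmap), channel_map = cmap),
            class = "enose_ranks")
}

#' @export
print.enose_ranks <- function(x, ...) {
  cat("<enose_ranks> ", ncol(x$per_method), " features x ",
      nrow(x$per_method), " methods; best sensors: ",
      paste(names(sort(x$sensor))[seq_len(min(5, length(x$sensor)))],
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a rank matrix as CSV
#' @param ranks an `enose_ranks` object.
#' @param path output CSV path.
#' @export
write_ranks <- function(ranks, path) {
  df <- data.frame(feature = colnames(ranks$per_method),
                   t(ranks$per_method),
                   ensemble = ranks$ensemble,
                   sensor = ranks$channel_map[colnames(ranks$per_method)],
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
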