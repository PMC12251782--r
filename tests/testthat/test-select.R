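# ensemble feature ranking and sensor-channel selection

test_that("mean-rank aggregation matches hand computation and is symmetric", {
  pm <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2), c(1, 3, 2))
  expect_equal(ensemble_rank(pm), c(1.75, 2.25, 2.0))
  expect_equal(ensemble_rank(pm[c(3, 1, 4, 2), ]), ensemble_rank(pm))
  expect_equal(ensemble_rank(rbind(c(2, 1, 3), c(2, 1, 3))), c(2, 1, 3))
  expect_error(ensemble_rank(list(c(1, 2), c(1, 2, 3))), "ragged")
})

test_that("sensor ranks average the feature ranks of each sensor", {
  ens <- setNames(1:9, paste0("A:f", 1:9))
  cmap <- setNames(rep("A", 9), names(ens))
  expect_equal(unname(sensor_rank(ens, cmap)), 5)
  ens2 <- setNames(c(1, 2, 3, 4, 5, 6), paste0(rep(c("A", "B"), each = 3), ":f", 1:3))
  cmap2 <- setNames(rep(c("A", "B"), each = 3), names(ens2))
  expect_equal(sensor_rank(ens2, cmap2), c(A = 2, B = 5), ignore_attr = TRUE)
  ens3 <- setNames(rep(2, 6), names(ens2))
  expect_true(all(sensor_rank(ens3, cmap2) == 2))
  expect_error(sensor_rank(setNames(1, "zz"), cmap2), "unmapped")
})

test_that("channel selection keeps the k best plus environment channels", {
  sr <- setNames(c(3, 1, 2, 5, 4), paste0("S", 1:5))
  expect_equal(select_channels(sr, k = 2), c("S2", "S3", "S22", "S23"))
  expect_equal(select_channels(sr, k = 5)[1:5], c("S2", "S3", "S1", "S5", "S4"))
  # the standard configuration emits 18 channels
  sr21 <- setNames(seq_len(21), paste0("S", 1:21))
  expect_length(select_channels(sr21, k = 16), 18)
  # deterministic alphanumeric tie-break
  tied <- setNames(rep(1, 3), c("S3", "S1", "S2"))
  expect_equal(select_channels(tied, k = 3, always_include = NULL)[1:3],
               c("S1", "S2", "S3"))
  expect_error(select_channels(sr, k = 0), "positive")
})

test_that("every ranker assigns perfect-correlation features rank 1", {
  set.seed(21)
  n <- 60
  Y <- matrix(runif(n * 8, 0, 10), n, 8)
  X <- cbind(f1 = Y[, 3], f2 = -Y[, 3], f3 = rnorm(n), f4 = rnorm(n))
  ft <- make_feature_table(X, Y, setNames(rep("P1", 4), colnames(X)))
  rp <- rank_features("pearson", ft)
  expect_equal(unname(sort(rp[c("f1", "f2")])), c(1.5, 1.5))  # tied at best
  rm <- rank_features("mic", ft)
  expect_true(all(rm[c("f1", "f2")] < rm[c("f3", "f4")]))
})

test_that("rank vectors keep the average-rank invariant mean (m+1)/2", {
  set.seed(22)
  n <- 40; m <- 12
  X <- matrix(rnorm(n * m), n, m,
              dimnames = list(NULL, paste0("f", 1:m)))
  X[, 3] <- 0  # constant column must still get a finite rank
  Y <- matrix(runif(n * 8), n, 8)
  ft <- make_feature_table(X, Y, setNames(rep(c("A", "B", "C"), each = 4),
                                          colnames(X)))
  for (mth in c("pearson", "mic", "rf", "svmrfe")) {
    r <- rank_features(mth, ft, seed = 1)
    expect_equal(mean(r), (m + 1) / 2, tolerance = 1e-12)
    expect_false(anyNA(r))
  }
  expect_error(rank_features("pearson", ft[1:10, ]), "20 samples")
})

test_that("a linearly generating feature is ranked first by all methods", {
  hits <- setNames(rep(0L, 4), c("pearson", "mic", "rf", "svmrfe"))
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 200
    Y <- matrix(runif(n * 8, 0, 10), n, 8)
    X <- cbind(gen = Y %*% runif(8, 0.5, 1) + rnorm(n, 0, 0.5),
               matrix(rnorm(n * 4), n, 4))
    colnames(X) <- paste0("f", 1:5)
    ft <- make_feature_table(X, Y, setNames(rep("P", 5), colnames(X)))
    for (mth in names(hits)) {
      r <- rank_features(mth, ft, seed = s)
      if (which.min(r) == 1L) hits[mth] <- hits[mth] + 1L
    }
  }
  expect_true(all(hits >= 0.9 * n_seeds))
})

test_that("improving one method's rank never worsens the ensemble rank", {
  pm <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 1, 4, 3), c(1, 4, 2, 3))
  base <- ensemble_rank(pm)
  pm2 <- pm
  pm2[2, 3] <- 1  # improve feature 3 under method 2
  expect_lte(ensemble_rank(pm2)[3], base[3])
  expect_equal(ensemble_rank(pm2)[-3], base[-3])
})

test_that("rank_ensemble recovers the planted informative sensor", {
  ft <- planted_features(n = 150, n_sensors = 5, informative = 2, seed = 3)
  rk <- rank_ensemble(ft, seed = 3)
  expect_equal(names(which.min(rk$sensor)), "P2")
  expect_equal(dim(rk$per_method), c(4L, 45L))
  # per-method rows carry the tie convention too
  expect_true(all(abs(rowMeans(rk$per_method) - 23) < 1e-9))
  sel <- select_channels(rk$sensor, k = 1, always_include = NULL)
  expect_equal(sel, "P2")
})
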