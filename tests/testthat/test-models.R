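# model builders, structural identities, training behavior, baselines

small_cfg <- function(name, seed = 2, ...) {
  model_config(name, L = 24, C = 5, conv = c(6, 8, 8), rnn_hidden = 4,
               dct_k = 8, comp_dim = 4, fc = 8, pool = 3, decomp_kernel = 5,
               seed = seed, ...)
}

test_that("every model maps (B, L, C) windows to B x 8 outputs", {
  set.seed(1)
  x <- array(rnorm(3 * 24 * 5), c(3, 24, 5))
  for (m in enosenet:::DEEP_MODELS) {
    g <- build_model(small_cfg(m))
    y <- g$fwd(x)
    expect_equal(dim(y), c(3L, 8L), label = m)
    dx <- g$bwd(matrix(1, 3, 8))
    expect_equal(dim(dx), dim(x), label = m)
  }
  expect_error(model_config("NOPE"), "unknown model")
  # underscore aliases accepted
  expect_equal(model_config("Bi_LSTM", L = 24, C = 5, pool = 3)$name, "BiLSTM")
})

test_that("parameter counts grow along the ablation chain", {
  np <- vapply(c("ED-CNN-LSTM", "ED-CNN-DCT-LSTM", "IED-CNN-LSTM"),
               function(m) n_parameters(build_model(small_cfg(m))),
               numeric(1))
  expect_true(all(diff(np) > 0))
})

test_that("full-model output is main output plus compensation", {
  set.seed(3)
  x <- array(rnorm(4 * 24 * 5), c(4, 24, 5))
  gi <- build_model(small_cfg("IED-CNN-LSTM", seed = 5))
  ge <- build_model(small_cfg("ED-CNN-DCT-LSTM", seed = 5))
  # share the main-path weights; compensation head is zero-initialized, so
  # at initialization the two models coincide exactly
  li <- enosenet:::.collect_layers(c(gi$main$cb,
          list(gi$main$b1, gi$main$b2, gi$main$proj, gi$main$attn,
               gi$main$dec1, gi$main$dec2, gi$main$f1, gi$main$f2)))
  le <- enosenet:::.collect_layers(c(ge$main$cb,
          list(ge$main$b1, ge$main$b2, ge$main$proj, ge$main$attn,
               ge$main$dec1, ge$main$dec2, ge$main$f1, ge$main$f2)))
  expect_length(li, length(le))
  for (i in seq_along(li)) le[[i]]$par <- li[[i]]$par
  expect_equal(gi$fwd(x), ge$fwd(x), tolerance = 1e-12)
  # a nonzero compensation head shifts the output additively
  gi$comp$cf2$par$b[] <- 0.25
  expect_equal(gi$fwd(x), ge$fwd(x) + 0.25, tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(4)
  x <- array(rnorm(20 * 24 * 5), c(20, 24, 5))
  y <- matrix(runif(20 * 8), 20, 8)
  cfg <- small_cfg("ED-CNN-LSTM", seed = 11, epochs = 2, batch = 8)
  f1 <- train_model(build_model(cfg), x, y)
  f2 <- train_model(build_model(cfg), x, y)
  p1 <- unlist(enosenet:::.get_params(f1$graph$layers))
  p2 <- unlist(enosenet:::.get_params(f2$graph$layers))
  expect_identical(p1, p2)
  expect_false(identical(
    p1, unlist(enosenet:::.get_params(
      train_model(build_model(small_cfg("ED-CNN-LSTM", seed = 12,
                                        epochs = 2, batch = 8)),
                  x, y)$graph$layers))))
})

test_that("the network can overfit a small window subset", {
  w <- tiny_windows(8, seed = 31)
  w <- w[seq_len(min(50, length(w)))]
  fit <- fit_enose(w, model = "ED-CNN-LSTM", conv = c(8, 12, 12),
                   rnn_hidden = 8, fc = 16, pool = 3, epochs = 300,
                   batch = 16, lr = 5e-3, seed = 1)
  y <- windows_to_arrays(w)$y
  rng <- max(y) - min(y)
  rmse <- sqrt(mean((fit$train_fitted - y)^2))
  expect_lt(rmse, 0.05 * rng)
  # training loss is finite and trends downward
  expect_true(all(is.finite(fit$history)))
  ma <- stats::filter(fit$history, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-4))
})

test_that("fitted models expose the standard S3 interface", {
  w <- tiny_windows(8, seed = 32)
  # a gas can stay absent in 10 windows, so the target scaler may warn
  fit <- suppressWarnings(
    fit_enose(w[1:10], model = "CNN-LSTM", conv = c(6, 8, 8),
              rnn_hidden = 4, fc = 8, pool = 3, epochs = 2, seed = 1))
  expect_s3_class(fit, "enose_net")
  pr <- predict(fit, w[11:12])
  expect_equal(dim(pr), c(2L, 8L))
  expect_equal(colnames(pr), enose_gases()$name)
  expect_equal(dim(residuals(fit)), c(10L, 8L))
  expect_type(coef(fit), "list")
  expect_output(print(fit), "CNN-LSTM")
  expect_output(summary(fit), "Parameters")
})

test_that("baseline regressors honor their fixed hyperparameters", {
  cfg <- baseline_config("RF")
  expect_equal(cfg$num_trees, 700)
  expect_equal(cfg$max_depth, 9)
  expect_equal(cfg$seed, 42)
  expect_equal(baseline_config("KNN")$k, 4)
  expect_equal(baseline_config("SVM")$cost, 50)
  xg <- baseline_config("XGBoost")
  expect_equal(c(xg$nrounds, xg$eta, xg$max_depth, xg$gamma),
               c(850, 0.025, 4, 0.026))
  expect_equal(baseline_config("MLP")$hidden, c(300, 150))
  expect_error(baseline_config("ZZZ"), "unknown baseline")
})

test_that("distance-weighted KNN returns training targets at zero distance", {
  ft <- planted_features(n = 40, n_sensors = 2, seed = 5)
  fit <- fit_baseline("KNN", ft)
  pr <- predict(fit, ft)
  y <- enosenet:::.features_xy(ft)$y
  expect_equal(unname(pr), unname(y), tolerance = 1e-10)
})

test_that("the RF baseline with a fixed seed is reproducible", {
  ft <- planted_features(n = 60, n_sensors = 2, seed = 6)
  f1 <- fit_baseline(baseline_config("RF", num_trees = 50), ft)
  f2 <- fit_baseline(baseline_config("RF", num_trees = 50), ft)
  expect_equal(predict(f1, ft), predict(f2, ft))
})

test_that("all five baselines learn the planted-signal feature set", {
  ft <- planted_features(n = 400, n_sensors = 3, seed = 7, noise_sd = 0.05)
  sp <- split_dataset(400, ratio = 0.8, seed = 7)
  restore <- function(d, idx) {
    out <- as.data.frame(d[idx, ], check.names = FALSE)
    attr(out, "channel_map") <- attr(d, "channel_map")
    attr(out, "feature_cols") <- attr(d, "feature_cols")
    class(out) <- class(d)
    out
  }
  tr <- restore(ft, sp$train); te <- restore(ft, sp$test)
  y_te <- enosenet:::.features_xy(te)$y
  for (b in c("KNN", "SVM", "RF", "XGBoost", "MLP")) {
    cfg <- switch(b,
      RF = baseline_config("RF", num_trees = 100),
      XGBoost = baseline_config("XGBoost", nrounds = 100),
      baseline_config(b))
    fit <- fit_baseline(cfg, tr)
    m <- compute_metrics(y_te, predict(fit, te))
    expect_gt(m$pooled["r2"], 0, label = b)
  }
})
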