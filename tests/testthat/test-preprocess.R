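# lag estimation, Kalman / Savitzky-Golay filtering, scaling, windowing

test_that("estimate_lag recovers exact shifts", {
  set.seed(1)
  x <- cumsum(rnorm(400))
  expect_equal(estimate_lag(x[1:300], x[1:300], max_lag = 50), 0L)
  delayed <- c(rep(x[1], 7), x)[1:300]
  expect_equal(estimate_lag(x[1:300], delayed, max_lag = 50), 7L)
  expect_error(estimate_lag(rep(1, 300), x[1:300], max_lag = 50),
               "constant")
})

test_that("estimate_lag tolerates noise at SNR 10", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    truth <- rep(c(0, 5, 0, 3, 0, 8), each = 60)
    resp <- c(rep(0, 7), truth)[seq_along(truth)]
    resp <- resp + rnorm(length(resp), 0, sd(truth) / sqrt(10))
    if (estimate_lag(truth, resp, max_lag = 30) == 7L) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("kalman filter fixes constants, tracks in the r->0 limit, denoises", {
  expect_equal(kalman_smooth(rep(3, 50), 1e-3, 1), rep(3, 50))
  set.seed(2)
  z <- rnorm(100)
  expect_equal(kalman_smooth(z, q = 1, r = 1e-12), z, tolerance = 1e-5)
  noisy <- 5 + rnorm(500)
  expect_lt(var(kalman_smooth(noisy, 1e-3, 1)), var(noisy))
  expect_error(kalman_smooth(1:5, q = 0, r = 1), "> 0")
})

test_that("savgol filter reproduces low-order polynomials and denoises", {
  expect_equal(savgol_smooth(c(1, 2, 3, 4, 5), 5, 2), c(1, 2, 3, 4, 5),
               tolerance = 1e-10)
  x <- (1:50)^2
  sm <- savgol_smooth(x, 11, 3)
  expect_equal(sm[6:45], x[6:45], tolerance = 1e-8)
  set.seed(3)
  clean <- sin(2 * pi * (1:300) / 60)
  noisy <- clean + rnorm(300, 0, 0.3)
  expect_lt(sqrt(mean((savgol_smooth(noisy, 11, 3) - clean)^2)),
            sqrt(mean((noisy - clean)^2)))
  expect_error(savgol_smooth(1:5, 11, 3), "shorter")
  expect_error(savgol_smooth(1:50, 10, 3), "odd")
})

test_that("preprocessing reduces error to the noise-free twin", {
  prof <- gen_intermittent(1, seed = 6)
  clean <- simulate_response(prof, default_array(noise_sd = 0), seed = 6,
                             drift = FALSE)
  noisy <- simulate_response(prof, default_array(), seed = 6, drift = FALSE)
  filt <- preprocess_recording(noisy)
  mse <- function(a, b) mean((a$channels[, 1:21] - b$channels[, 1:21])^2)
  expect_lt(mse(filt, clean), mse(noisy, clean))
  # length and channel order preserved, no NAs
  expect_equal(dim(filt$channels), dim(noisy$channels))
  expect_identical(colnames(filt$channels), colnames(noisy$channels))
  expect_false(anyNA(filt$channels))
})

test_that("a near-identity filter configuration leaves the recording intact", {
  prof <- gen_intermittent(1, seed = 8)
  rec <- simulate_response(prof, seed = 8)
  cfg <- filter_config(lag_s = 0, kalman_q = 1, kalman_r = 1e-12,
                       sg_window = 1, sg_order = 0)
  out <- preprocess_recording(rec, cfg)
  expect_equal(out$channels, rec$channels, tolerance = 1e-6)
})

test_that("lag alignment moves the cross-correlation peak to zero", {
  set.seed(9)
  n <- 600
  truth <- rep(c(0, 6, 0, 4, 0, 9), each = 100)
  resp <- c(rep(0, 12), truth)[1:n] + rnorm(n, 0, 0.3)
  expect_equal(estimate_lag(truth, resp, 40), 12L)
  shifted <- enosenet:::.shift_left(resp, 12L)
  expect_equal(estimate_lag(truth, shifted, 40), 0L)
})

test_that("min-max scaler follows the normalization identity", {
  sc <- fit_scaler(matrix(c(0, 5, 10), ncol = 1))
  expect_equal(as.numeric(apply_scaler(sc, matrix(c(0, 5, 10)))),
               c(0, 0.5, 1))
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  sc2 <- fit_scaler(X)
  expect_equal(invert_scaler(sc2, apply_scaler(sc2, X)), X,
               tolerance = 1e-12)
  # train-fitted scaler: train columns map exactly onto [0, 1]
  Z <- apply_scaler(sc2, X)
  expect_equal(unname(apply(Z, 2, min)), rep(0, 3))
  expect_equal(unname(apply(Z, 2, max)), rep(1, 3))
  # out-of-range values are not clipped
  expect_gt(apply_scaler(sc2, matrix(max(X[, 1]) + 5, 1, 3))[1, 1], 1)
  expect_warning(fit_scaler(cbind(1:5, rep(2, 5))), "constant")
})

test_that("windowize tiles recordings with the documented stride rule", {
  prof <- gen_continuous(2, seed = 5, opts = list(clean = 120,
                                                  hold = c(120, 120)))
  rec <- simulate_response(prof, seed = 5)  # T = 360
  expect_length(windowize(rec, length = 180, stride = 180), 2)
  expect_length(windowize(rec, length = 180, stride = 30), 7)
  expect_error(windowize(rec, length = 999), "shorter")
  # last-step labeling picks up the post-step concentration
  w <- windowize(rec, length = 180, stride = 30)
  i_end <- w[[7]]$origin$start + 179
  expect_equal(unname(w[[7]]$target), unname(rec$truth[i_end, ]))
  # mean labeling averages within the window
  wm <- windowize(rec, length = 180, stride = 180, labeling = "mean")
  expect_equal(unname(wm[[1]]$target),
               unname(colMeans(rec$truth[1:180, ])))
})

test_that("windows round-trip through CSV shards and a manifest", {
  w <- tiny_windows(3, seed = 13)[1:3]
  dir <- file.path(tempdir(), "win_shards")
  write_windows(w, dir, scaler = fit_scaler(w[[1]]$values))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_windows(dir)
  expect_length(back, 3)
  expect_equal(unname(back[[2]]$values), unname(w[[2]]$values))
  expect_equal(colnames(back[[2]]$values), colnames(w[[2]]$values))
  expect_equal(back[[3]]$target, w[[3]]$target, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
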