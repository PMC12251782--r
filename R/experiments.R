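# Canned scaled-down benchmark experiments on synthetic recordings, shared
# by the test-suite and the acceptance script.

#' Default model input channel set
#'
#' The 16 gas channels plus the two environment channels used as the
#' standard model input configuration (the channel set identified by the
#' intermittent channel-selection study).
#'
#' @return character vector of 18 channel ids.
#' @export
default_channels <- function() {
  c(paste0("S", c(1:7, 10:17, 19)), "S22", "S23")
}

#' Build a scaled-down continuous-detection benchmark dataset
#'
#' Simulates a non-intermittent recording, preprocesses it with the default
#' filter chain, cuts 180-s windows at the default 30-s stride, and splits
#' 80/20 at random. Problem sizes default to the package's scaled benchmark
#' (about 60 step conditions, a few hundred windows).
#'
#' @param n_conditions number of random step conditions.
#' @param seed RNG seed (drives profile, response, and split).
#' @param drift enable short-term drift in the simulator.
#' @param window,stride windowing parameters (s).
#' @param channels model input channels.
#' @return list with `train`, `test` (window lists), `channels`,
#'   `recording`.
#' @export
benchmark_dataset <- function(n_conditions = 60, seed = 1, drift = FALSE,
                              window = 180, stride = 30,
                              channels = default_channels()) {
  prof <- gen_continuous(n_conditions, seed = seed)
  rec <- simulate_response(prof, default_array(), seed = seed + 1000L,
                           drift = drift)
  rec <- preprocess_recording(rec)
  w <- windowize(rec, length = window, stride = stride)
  sp <- split_dataset(w, ratio = 0.8, seed = seed + 2000L)
  list(train = sp$train, test = sp$test, channels = channels,
       recording = rec)
}

#' Feature table with one informative sensor (planted-signal fixture)
#'
#' Builds a synthetic feature table in which the nine features of a single
#' sensor are (noisy, partly nonlinear) transforms of the targets while all
#' other sensors carry pure noise. Used to test that the ensemble ranking
#' recovers the informative sensor.
#'
#' @param n samples.
#' @param n_sensors sensors (9 features each).
#' @param informative id (index) of the informative sensor.
#' @param seed RNG seed.
#' @param noise_sd noise added to the informative features.
#' @return `enose_features` table with sensors named P1..Pk.
#' @export
planted_features <- function(n = 150, n_sensors = 5, informative = 1,
                             seed = 1, noise_sd = 0.1) {
  set.seed(seed)
  y <- matrix(runif(n * N_GASES, 0, 10), n, N_GASES)
  colnames(y) <- GAS_NAMES
  sensors <- paste0("P", seq_len(n_sensors))
  cols <- as.vector(t(outer(sensors, FEATURE_NAMES, paste, sep = ":")))
  X <- matrix(rnorm(n * length(cols)), n, length(cols),
              dimnames = list(NULL, cols))
  # informative sensor: each feature responds to a mix of the targets
  base <- informative
  mix <- matrix(runif(9 * N_GASES, 0.2, 1), 9, N_GASES)
  sig <- y %*% t(mix)
  sig[, 4] <- sqrt(pmax(sig[, 4], 0))          # mildly nonlinear features
  sig[, 5] <- log1p(pmax(sig[, 5], 0))
  X[, (base - 1) * 9 + seq_len(9)] <-
    scale(sig) + rnorm(n * 9, 0, noise_sd)
  out <- as.data.frame(cbind(X, `colnames<-`(y, paste0("y_", GAS_NAMES))),
                       check.names = FALSE)
  attr(out, "channel_map") <- setNames(rep(sensors, each = 9), cols)
  attr(out, "feature_cols") <- cols
  class(out) <- c("enose_features", "data.frame")
  out
}

#' Scaled training configuration for benchmark experiments
#'
#' Reduced architecture and training recipe used in the package's synthetic
#' benchmarks: conv widths (16, 32, 32) at recurrent width 32 for
#' single-model recovery runs, or (8, 16, 16) at width 16 for the
#' multi-model drift comparison; both train 30 epochs with Adam at 5e-3,
#' batch 16, under the engine's cosine schedule.
#'
#' @param size `"recovery"` (hidden 32) or `"comparison"` (hidden 16).
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @param ... further [model_config()] overrides.
#' @return list of overrides to pass to [fit_enose()].
#' @export
scaled_overrides <- function(size = c("recovery", "comparison"),
                             epochs = 30, seed = 1, ...) {
  size <- match.arg(size)
  base <- if (size == "recovery") {
    list(conv = c(16, 32, 32), rnn_hidden = 32, fc = 64, comp_dim = 16,
         dct_k = 16, lr = 5e-3, batch = 16, epochs = epochs, seed = seed)
  } else {
    list(conv = c(8, 16, 16), rnn_hidden = 16, fc = 32, comp_dim = 8,
         dct_k = 16, lr = 5e-3, batch = 16, epochs = epochs, seed = seed)
  }
  utils::modifyList(base, list(...))
}
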