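# Lag alignment, Kalman -> Savitzky-Golay filtering, min-max scaling and
# sliding-window sample construction.

#' Filter configuration
#'
#' @param lag_s nonnegative integer lag (s) applied to gas channels.
#' @param kalman_q,kalman_r process / measurement noise variances (> 0).
#' @param sg_window odd Savitzky-Golay window length; `1` disables smoothing.
#' @param sg_order polynomial order (< `sg_window`).
#' @return list of class `enose_filter_config`.
#' @export
filter_config <- function(lag_s = 0, kalman_q = 3, kalman_r = 1,
                          sg_window = 11, sg_order = 3) {
  stopifnot(lag_s >= 0, lag_s == round(lag_s))
  if (kalman_q <= 0 || kalman_r <= 0) stop("kalman_q and kalman_r must be > 0")
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_window > 1 && sg_order >= sg_window) stop("sg_order must be < sg_window")
  structure(list(lag_s = as.integer(lag_s), kalman_q = kalman_q,
                 kalman_r = kalman_r, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "enose_filter_config")
}

#' Estimate sensor lag by cross-correlation
#'
#' Returns the delay (in samples, 0..`max_lag`) maximizing the correlation
#' between the concentration input and the delayed sensor response.
#'
#' @param truth_series concentration input series.
#' @param response_series sensor response series (same length).
#' @param max_lag maximum lag to scan; series must be at least `2 * max_lag`
#'   long.
#' @return integer lag in seconds.
#' @export
estimate_lag <- function(truth_series, response_series, max_lag = 60) {
  n <- length(truth_series)
  stopifnot(length(response_series) == n, n >= 2 * max_lag)
  if (sd(truth_series) == 0 || sd(response_series) == 0) {
    stop("cross-correlation undefined for constant series")
  }
  cc <- vapply(0:max_lag, function(l) {
    a <- truth_series[1:(n - l)]
    b <- response_series[(1 + l):n]
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  as.integer(which.max(cc) - 1L)
}

#' Scalar random-walk Kalman smoother
#'
#' One-dimensional Kalman filter with a random-walk state model
#' (`x_t = x_{t-1} + w`, `w ~ N(0, q)`; `z_t = x_t + v`, `v ~ N(0, r)`),
#' the state-estimation stage of the preprocessing chain.
#'
#' @param series numeric series (finite).
#' @param q process noise variance (> 0).
#' @param r measurement noise variance (> 0).
#' @return filtered series, same length.
#' @export
kalman_smooth <- function(series, q = 1e-3, r = 1) {
  if (q <= 0 || r <= 0) stop("q and r must be > 0")
  stopifnot(all(is.finite(series)))
  n <- length(series)
  out <- numeric(n)
  x <- series[1]
  P <- r
  out[1] <- x
  if (n > 1) {
    for (t in 2:n) {
      P <- P + q
      K <- P / (P + r)
      x <- x + K * (series[t] - x)
      P <- (1 - K) * P
      out[t] <- x
    }
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()]
#' (edges handled by the filter's transient-corrected projection matrix).
#' `window = 1` returns the input unchanged.
#'
#' @param series numeric series of length >= `window`.
#' @param window odd window length.
#' @param order polynomial order (< `window`).
#' @return smoothed series.
#' @export
savgol_smooth <- function(series, window = 11, order = 3) {
  if (window %% 2 != 1) stop("window must be odd")
  if (window == 1) return(series)
  if (order >= window) stop("order must be < window")
  if (length(series) < window) stop("series shorter than window")
  as.numeric(signal::sgolayfilt(series, p = order, n = window))
}

# advance a series by `lag` samples (response lags the input, so aligning
# means shifting the response earlier); the tail is padded with the last value
.shift_left <- function(x, lag) {
  n <- length(x)
  if (lag == 0 || n == 0) return(x)
  lag <- min(lag, n - 1L)
  c(x[(lag + 1L):n], rep(x[n], lag))
}

#' Preprocess a recording
#'
#' Gas channels are lag-aligned (shifted earlier by `lag_s`), then filtered
#' by the scalar Kalman filter followed by Savitzky-Golay smoothing.
#' Environment channels are smoothed but never lag-shifted. The truth matrix
#' is untouched.
#'
#' @param recording an `enose_recording`.
#' @param config an `enose_filter_config`.
#' @param env_channels channel ids treated as environment channels (default
#'   S22, S23).
#' @return a filtered `enose_recording`.
#' @export
preprocess_recording <- function(recording, config = filter_config(),
                                 env_channels = c("S22", "S23")) {
  stopifnot(inherits(recording, "enose_recording"),
            inherits(config, "enose_filter_config"))
  ch <- recording$channels
  out <- ch
  is_env <- colnames(ch) %in% env_channels
  for (i in seq_len(ncol(ch))) {
    x <- as.numeric(ch[, i])
    if (!is_env[i] && config$lag_s > 0) x <- .shift_left(x, config$lag_s)
    x <- kalman_smooth(x, config$kalman_q, config$kalman_r)
    if (config$sg_window > 1) {
      x <- savgol_smooth(x, config$sg_window, config$sg_order)
    }
    out[, i] <- x
  }
  recording$channels <- out
  recording$provenance$preprocessed <- unclass(config)
  recording
}

#' Min-max scaler
#'
#' Learns per-column minima and maxima on a fitting set; `apply_scaler` maps
#' each fitted column to `[0, 1]` on that set (values outside the fitted
#' range are NOT clipped), `invert_scaler` restores the original units.
#' Constant columns map to 0 (with a warning at fit time).
#'
#' @param x numeric matrix (rows = observations).
#' @return object of class `enose_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("fitting set is empty")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs == mins)) {
    warning("constant column(s) in scaler fit; they will map to 0: ",
            paste(which(maxs == mins), collapse = ", "))
  }
  structure(list(min = mins, max = maxs), class = "enose_scaler")
}

#' @rdname fit_scaler
#' @param scaler an `enose_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "enose_scaler"))
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1  # constant columns -> 0
  sweep(sweep(x, 2, scaler$min, `-`), 2, rng, `/`)
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "enose_scaler"))
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, rng, `*`), 2, scaler$min, `+`)
}

#' Cut a recording into fixed-length sample windows
#'
#' Windows start at offsets `0, stride, 2 stride, ...` subject to
#' `start + length <= T`. The target of a window is the true concentration
#' vector at its final time step (`labeling = "last"`, the online-detector
#' convention) or the per-gas mean over the window (`labeling = "mean"`).
#'
#' @param recording an `enose_recording`.
#' @param length window length in samples (600 intermittent, 180 continuous).
#' @param stride step between window starts (>= 1).
#' @param labeling `"last"` (default) or `"mean"`.
#' @param id recording identifier stored in each window's origin.
#' @return list of `enose_window` objects: `values` (L x C), `target`
#'   (8-vector), `origin`.
#' @export
windowize <- function(recording, length = 180, stride = 30,
                      labeling = c("last", "mean"), id = "rec") {
  labeling <- match.arg(labeling)
  stopifnot(stride >= 1)
  n <- nrow(recording$channels)
  if (length > n) stop("recording shorter than window length")
  starts <- seq(1L, n - length + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + length - 1L)
    target <- if (labeling == "last") {
      recording$truth[idx[length], ]
    } else colMeans(recording$truth[idx, , drop = FALSE])
    structure(list(values = recording$channels[idx, , drop = FALSE],
                   target = target,
                   origin = list(id = id, start = s)),
              class = "enose_window")
  })
}

# Stack a list of windows into an (N, L, C) array restricted to `channels`,
# plus the (N, 8) target matrix.
#' Convert windows to model-ready arrays
#'
#' @param windows list of `enose_window`.
#' @param channels channel ids to keep, in order (default: all).
#' @return list with `x` (N x L x C array) and `y` (N x 8 matrix).
#' @export
windows_to_arrays <- function(windows, channels = NULL) {
  stopifnot(length(windows) > 0)
  v1 <- windows[[1]]$values
  if (is.null(channels)) channels <- colnames(v1)
  missing_ch <- setdiff(channels, colnames(v1))
  if (length(missing_ch)) stop("channels not present: ",
                               paste(missing_ch, collapse = ", "))
  L <- nrow(v1); C <- length(channels); N <- length(windows)
  x <- array(0, dim = c(N, L, C), dimnames = list(NULL, NULL, channels))
  y <- matrix(0, N, N_GASES, dimnames = list(NULL, GAS_NAMES))
  for (i in seq_len(N)) {
    x[i, , ] <- windows[[i]]$values[, channels]
    y[i, ] <- windows[[i]]$target
  }
  list(x = x, y = y)
}

#' Serialize sample windows to a directory of CSV shards
#'
#' Writes one CSV per window (`window_00001.csv`, ... with one column per
#' channel), a `targets.csv` with the per-window 8-gas targets, and a
#' `manifest.json` recording window length, channel list, origins and
#' (optionally) the scaler parameters used to normalize them.
#'
#' @param windows list of `enose_window`.
#' @param dir output directory (created if needed).
#' @param scaler optional `enose_scaler` stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_windows <- function(windows, dir, scaler = NULL) {
  stopifnot(length(windows) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(windows)) {
    utils::write.csv(as.data.frame(windows[[i]]$values),
                     file.path(dir, sprintf("window_%05d.csv", i)),
                     row.names = FALSE)
  }
  tg <- do.call(rbind, lapply(windows, function(w) w$target))
  colnames(tg) <- GAS_NAMES
  utils::write.csv(as.data.frame(tg), file.path(dir, "targets.csv"),
                   row.names = FALSE)
  manifest <- list(
    n = length(windows),
    length = nrow(windows[[1]]$values),
    channels = colnames(windows[[1]]$values),
    origins = lapply(windows, function(w) w$origin),
    scaler = if (!is.null(scaler)) list(min = unname(scaler$min),
                                        max = unname(scaler$max))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_windows
#' @export
read_windows <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tg <- as.matrix(utils::read.csv(file.path(dir, "targets.csv")))
  lapply(seq_len(manifest$n), function(i) {
    v <- as.matrix(utils::read.csv(file.path(dir,
                                             sprintf("window_%05d.csv", i)),
                                   check.names = FALSE))
    structure(list(values = v, target = setNames(tg[i, ], GAS_NAMES),
                   origin = as.list(manifest$origins[i, , drop = FALSE])),
              class = "enose_window")
  })
}
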