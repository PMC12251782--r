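# The nine per-channel time- and frequency-domain window features used for
# classical baselines and for feature/channel selection.

FEATURE_NAMES <- c("integral", "differential", "avg_differential",
                   "maximum", "minimum", "mean",
                   "barycenter_freq", "avg_freq", "max_freq")

#' Six time-domain features of a response window
#'
#' `integral` = sum(x) * dt (dt = 1 s); `differential` = maximum first
#' difference (max response slope); `avg_differential` = mean absolute first
#' difference; plus `maximum`, `minimum`, `mean`.
#'
#' @param series numeric series of length >= 2.
#' @param differential `"max"` (default, max slope) or `"net"` (last minus
#'   first); `avg_differential` `"abs"` (default) or `"signed"`.
#' @param avg_differential see above.
#' @return named numeric vector of 6 features.
#' @export
time_features <- function(series, differential = c("max", "net"),
                          avg_differential = c("abs", "signed")) {
  differential <- match.arg(differential)
  avg_differential <- match.arg(avg_differential)
  if (length(series) < 2) stop("series must have length >= 2")
  d <- diff(series)
  c(integral = sum(series),
    differential = if (differential == "max") max(d) else
      series[length(series)] - series[1],
    avg_differential = if (avg_differential == "abs") mean(abs(d)) else mean(d),
    maximum = max(series),
    minimum = min(series),
    mean = mean(series))
}

#' Three frequency-domain features of a response window
#'
#' The series is demeaned and Hann-windowed, then the one-sided power
#' spectrum `P_k` and amplitude spectrum `A_k` are computed by FFT.
#' Barycenter frequency = `sum(f P) / sum(P)`; average frequency =
#' `sum(f A) / sum(A)`; maximum frequency = `argmax_k P_k`. A spectrum that
#' is identically zero (e.g. a constant input) yields `(0, 0, 0)` with a
#' warning.
#'
#' @param series numeric series of length >= 4.
#' @param fs sampling frequency in Hz (default 1).
#' @return named numeric vector `(barycenter_freq, avg_freq, max_freq)`,
#'   each in `[0, fs/2]`.
#' @export
freq_features <- function(series, fs = 1) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4")
  x <- series - mean(series)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- fft(x * hann)
  half <- floor(n / 2) + 1L
  A <- Mod(X)[seq_len(half)]
  P <- A^2
  f <- (seq_len(half) - 1) * fs / n
  if (sum(P) == 0) {
    warning("all-zero spectrum; frequency features set to 0")
    return(c(barycenter_freq = 0, avg_freq = 0, max_freq = 0))
  }
  c(barycenter_freq = sum(f * P) / sum(P),
    avg_freq = sum(f * A) / sum(A),
    max_freq = f[which.max(P)])
}

#' Extract the 9-feature-per-channel table from sample windows
#'
#' @param windows nonempty list of `enose_window`.
#' @param channels gas channel ids to extract from (default: every channel
#'   except S22/S23).
#' @param fs sampling frequency (Hz).
#' @return object of class `enose_features`: data.frame with
#'   `<channel>:<feature>` columns followed by `y_<gas>` target columns;
#'   attribute `channel_map` maps feature column -> channel.
#' @export
extract_features <- function(windows, channels = NULL, fs = 1) {
  stopifnot(length(windows) > 0)
  all_ch <- colnames(windows[[1]]$values)
  if (is.null(channels)) channels <- setdiff(all_ch, c("S22", "S23"))
  if (length(channels) == 0) stop("empty channel subset")
  missing_ch <- setdiff(channels, all_ch)
  if (length(missing_ch)) stop("channels not present: ",
                               paste(missing_ch, collapse = ", "))
  cols <- as.vector(t(outer(channels, FEATURE_NAMES, paste, sep = ":")))
  feats <- matrix(0, length(windows), length(cols),
                  dimnames = list(NULL, cols))
  targets <- matrix(0, length(windows), N_GASES,
                    dimnames = list(NULL, paste0("y_", GAS_NAMES)))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    row <- unlist(lapply(channels, function(ch) {
      x <- as.numeric(w$values[, ch])
      c(time_features(x), suppressWarnings(freq_features(x, fs)))
    }))
    feats[i, ] <- row
    targets[i, ] <- w$target
  }
  out <- as.data.frame(cbind(feats, targets), check.names = FALSE)
  attr(out, "channel_map") <- setNames(rep(channels, each = length(FEATURE_NAMES)),
                                       cols)
  attr(out, "feature_cols") <- cols
  class(out) <- c("enose_features", "data.frame")
  out
}

#' @export
print.enose_features <- function(x, ...) {
  cols <- attr(x, "feature_cols")
  cat("<enose_features> ", nrow(x), " samples x ", length(cols),
      " feature columns (", length(unique(attr(x, "channel_map"))),
      " channels x ", length(FEATURE_NAMES), " features)\n", sep = "")
  invisible(x)
}

# split an enose_features object into X matrix and Y matrix
.features_xy <- function(ft) {
  cols <- attr(ft, "feature_cols")
  list(x = as.matrix(ft[, cols, drop = FALSE]),
       y = as.matrix(ft[, paste0("y_", GAS_NAMES), drop = FALSE]))
}

#' Write a feature table to CSV
#' @param ft an `enose_features` object.
#' @param path output path.
#' @export
write_features <- function(ft, path) {
  write.csv(as.data.frame(ft), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
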