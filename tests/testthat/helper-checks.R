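# shared test utilities: finite-difference gradient checking and small
# synthetic fixtures (all generated in code)

ns <- asNamespace("enosenet")

# relative finite-difference check of a layer's input and parameter
# gradients against its backward pass
grad_check_layer <- function(layer, x, n_input = 10, n_par = 5,
                             eps = 1e-6, seed = 42) {
  set.seed(seed)
  y <- layer$fwd(x)
  dy <- array(rnorm(length(y)), dim = dim(y) %||% length(y))
  dx <- layer$bwd(dy)
  lossf <- function(xx) sum(layer$fwd(xx) * dy)
  rel_err <- function(num, ana) abs(num - ana) / max(1, abs(num))
  errs <- vapply(sample(length(x), min(n_input, length(x))), function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    rel_err((lossf(x1) - lossf(x2)) / (2 * eps), dx[i])
  }, numeric(1))
  layer$fwd(x); layer$bwd(dy)  # restore caches/grads
  perr <- c(0)
  for (l in ns$.collect_layers(list(layer))) {
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      for (i in sample(length(g), min(n_par, length(g)))) {
        p0 <- l$par[[nm]][i]
        l$par[[nm]][i] <- p0 + eps; f1 <- lossf(x)
        l$par[[nm]][i] <- p0 - eps; f2 <- lossf(x)
        l$par[[nm]][i] <- p0
        perr <- c(perr, rel_err((f1 - f2) / (2 * eps), g[i]))
      }
    }
  }
  max(c(errs, perr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-pulse exposure profile built directly (no RNG)
two_pulse_profile <- function(conc = 6, gas = "hydrogen_sulfide",
                              pre = 150, pulse = 120, gap = 100,
                              post = 250) {
  n <- pre + pulse + gap + pulse + post
  cm <- matrix(0, n, 8)
  colnames(cm) <- enose_gases()$name
  j <- match(gas, colnames(cm))
  s1 <- pre + seq_len(pulse)
  s2 <- pre + pulse + gap + seq_len(pulse)
  cm[s1, j] <- conc
  cm[s2, j] <- conc
  seg <- data.frame(
    start = c(1, min(s1), max(s1) + 1, min(s2), max(s2) + 1),
    end = c(pre, max(s1), min(s2) - 1, max(s2), n),
    mode = c("clean", "gas", "clean", "gas", "clean"))
  structure(list(time = seq_len(n) - 1, conc = cm,
                 temp = rep(25, n), rh = rep(50, n),
                 press = rep(101.3, n), segments = seg),
            class = "enose_profile")
}

# minimal feature table from raw matrices (for ranking tests)
make_feature_table <- function(X, Y, channel_map) {
  colnames(Y) <- paste0("y_", enose_gases()$name)
  out <- as.data.frame(cbind(X, Y), check.names = FALSE)
  attr(out, "channel_map") <- channel_map
  attr(out, "feature_cols") <- colnames(X)
  class(out) <- c("enose_features", "data.frame")
  out
}

# small preprocessed window set for model tests (deterministic)
tiny_windows <- function(n_conditions = 6, seed = 7, drift = FALSE,
                         window = 60, stride = 60) {
  prof <- gen_continuous(n_conditions, seed = seed,
                         opts = list(clean = 120, hold = c(60, 120)))
  rec <- simulate_response(prof, default_array(), seed = seed + 1,
                           drift = drift)
  rec <- preprocess_recording(rec)
  windowize(rec, length = window, stride = stride)
}
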