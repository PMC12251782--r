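# Deep model roster: CNN / LSTM / Bi-LSTM / CNN-LSTM / CNN-Bi-LSTM /
# ED-CNN-LSTM / ED-CNN-DCT-LSTM / IED-CNN-LSTM builders, the training loop
# and the fitted-model S3 interface.

DEEP_MODELS <- c("CNN", "LSTM", "BiLSTM", "CNN-LSTM", "CNN-BiLSTM",
                 "ED-CNN-LSTM", "ED-CNN-DCT-LSTM", "IED-CNN-LSTM")

#' Deep model configuration
#'
#' Architecture and training hyperparameters shared by every model in the
#' roster (the fairness rule of the benchmark: common parameters are set to
#' common values).
#'
#' @param name model name, one of `r paste(DEEP_MODELS, collapse = ", ")`
#'   (aliases with underscores, e.g. `"Bi_LSTM"`, are accepted).
#' @param L input window length (time steps).
#' @param C input channel count.
#' @param conv the three 1-D convolution widths.
#' @param kernel convolution kernel size (odd).
#' @param rnn_hidden recurrent hidden units.
#' @param dct_k retained DCT coefficients in the channel attention.
#' @param attn_reduction attention bottleneck reduction ratio.
#' @param decomp_kernel moving-average width of the compensation branch
#'   decomposition (odd).
#' @param trans_heads,trans_ff transformer heads / feed-forward width.
#' @param comp_dim working width of the compensation branch.
#' @param fc fully connected head width.
#' @param pool temporal average-pooling factor applied to the sequence fed
#'   into a recurrent stack that consumes convolutional or fused encodings
#'   (must divide L; 1 disables).
#' @param lr,batch,epochs,seed Adam learning rate, batch size, training
#'   epochs, RNG seed.
#' @param clip global-norm gradient clipping threshold.
#' @param skip add a skip connection from the encoding's final time step to
#'   the regression head (encoder-decoder family only).
#' @param augment sd of Gaussian noise added to (normalized) training
#'   inputs each step, emulating sensor noise; 0 disables.
#' @param avg_tail fraction of final epochs whose parameters are averaged
#'   into the returned model (0 disables).
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient.
#' @return list of class `enose_model_config`.
#' @export
model_config <- function(name = "IED-CNN-LSTM", L = 180, C = 18,
                         conv = c(32, 64, 64), kernel = 3, rnn_hidden = 64,
                         dct_k = 16, attn_reduction = 4, decomp_kernel = 25,
                         trans_heads = 4, trans_ff = NULL, comp_dim = 16,
                         fc = 64, pool = 3, lr = 2e-3, batch = 32,
                         epochs = 100, clip = 5, skip = TRUE,
                         augment = 0, avg_tail = 0, weight_decay = 1e-3,
                         seed = 1) {
  name <- gsub("_", "", toupper(name))
  lut <- setNames(DEEP_MODELS, gsub("[_-]", "", toupper(DEEP_MODELS)))
  name <- lut[gsub("-", "", name)]
  if (is.na(name)) stop("unknown model name")
  if (decomp_kernel %% 2 != 1) stop("decomp_kernel must be odd")
  if (dct_k > L) stop("dct_k must be <= window length L")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  if (pool < 1 || L %% pool != 0) {
    stop("pool must be a positive divisor of the window length L")
  }
  structure(list(name = unname(name), L = L, C = C, conv = conv,
                 kernel = kernel, rnn_hidden = rnn_hidden, dct_k = dct_k,
                 attn_reduction = attn_reduction,
                 decomp_kernel = min(decomp_kernel, L - (1 - L %% 2)),
                 trans_heads = trans_heads,
                 trans_ff = trans_ff %||% (2 * comp_dim),
                 comp_dim = comp_dim, fc = fc, pool = pool, lr = lr,
                 batch = batch, epochs = epochs, clip = clip,
                 skip = isTRUE(skip), augment = augment,
                 avg_tail = avg_tail, weight_decay = weight_decay,
                 seed = seed, n_out = N_GASES),
            class = "enose_model_config")
}

# conv block: three 1-D convolutions + layer normalization, ReLU
# nonlinearities
.conv_block <- function(cfg) {
  list(
    c1 = nn_conv1d(cfg$C, cfg$conv[1], cfg$kernel, act = "relu"),
    c2 = nn_conv1d(cfg$conv[1], cfg$conv[2], cfg$kernel, act = "relu"),
    c3 = nn_conv1d(cfg$conv[2], cfg$conv[3], cfg$kernel, act = "linear"),
    ln = nn_layernorm(cfg$conv[3]),
    act = nn_act("relu")
  )
}

.seq_fwd <- function(layers, x) {
  for (l in layers) x <- l$fwd(x)
  x
}
.seq_bwd <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$bwd(dy)
  dy
}

# regression head: LSTM decoder output or flattened features -> 8 gases
.fc_head <- function(n_in, cfg) {
  list(f1 = nn_dense(n_in, cfg$fc, act = "relu"),
       f2 = nn_dense(cfg$fc, cfg$n_out, act = "linear"))
}

#' Build a deep model from a configuration
#'
#' The full IED-CNN-LSTM comprises: an Encoder of two parallel branches
#' (CNN block: three 1-D convolutions + layer normalization with ReLU;
#' Bi-LSTM block: two bidirectional recurrent layers) fused by feature-axis
#' concatenation and a linear projection; DCT channel attention on the fused
#' encoding; a Decoder of two unidirectional LSTM layers and fully connected
#' layers to the 8 gas outputs; and an external compensation branch that
#' decomposes the raw input window into trend (-> position-wise MLP) and
#' seasonal (-> one transformer encoder layer) parts, fuses them, applies
#' DCT attention, and maps the flattened result to an 8-vector added to the
#' decoder output. Ablations drop components accordingly (ED-CNN-LSTM: no
#' attention, no compensation; ED-CNN-DCT-LSTM: + attention;
#' IED-CNN-LSTM: + compensation).
#'
#' @param cfg an `enose_model_config`.
#' @return internal graph object (class `enose_nn_graph`) with `$fwd`,
#'   `$bwd`, `$layers`, `$cfg`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "enose_model_config"))
  set.seed(cfg$seed)
  name <- cfg$name
  H <- cfg$rnn_hidden
  g <- new.env(parent = emptyenv())
  g$cfg <- cfg

  if (name == "CNN") {
    cb <- .conv_block(cfg)
    fl <- nn_flatten()
    head <- .fc_head(cfg$L * cfg$conv[3], cfg)
    g$layers <- c(cb, list(fl = fl), head)
    g$fwd <- function(x) .seq_fwd(g$layers, x)
    g$bwd <- function(dy) .seq_bwd(g$layers, dy)
  } else if (name %in% c("LSTM", "BiLSTM", "CNN-LSTM", "CNN-BiLSTM")) {
    pre <- if (grepl("^CNN", name)) .conv_block(cfg) else list()
    if (length(pre) && cfg$pool > 1) {
      pre <- c(pre, list(pool = nn_avgpool1d(cfg$pool)))
    }
    rnn_in <- if (length(pre)) cfg$conv[3] else cfg$C
    bi <- grepl("BiLSTM", name)
    if (bi) {
      r1 <- nn_bilstm(rnn_in, H, "seq")
      r2 <- nn_bilstm(2 * H, H, "last")
      head <- .fc_head(2 * H, cfg)
    } else {
      r1 <- nn_lstm(rnn_in, H, "seq")
      r2 <- nn_lstm(H, H, "last")
      head <- .fc_head(H, cfg)
    }
    g$layers <- c(pre, list(r1 = r1, r2 = r2), head)
    g$fwd <- function(x) .seq_fwd(g$layers, x)
    g$bwd <- function(dy) .seq_bwd(g$layers, dy)
  } else {
    # encoder-decoder family
    cb <- .conv_block(cfg)
    b1 <- nn_bilstm(cfg$C, H, "seq")
    b2 <- nn_bilstm(2 * H, H, "seq")
    d_enc <- 2 * H
    proj <- nn_conv1d(cfg$conv[3] + 2 * H, d_enc, 1)
    attn <- if (name != "ED-CNN-LSTM") {
      nn_dct_attention(d_enc, cfg$L, cfg$dct_k, cfg$attn_reduction)
    } else NULL
    pl <- if (cfg$pool > 1) nn_avgpool1d(cfg$pool) else NULL
    dec1 <- nn_lstm(d_enc, H, "seq")
    dec2 <- nn_lstm(H, H, "last")
    head <- .fc_head(H + if (cfg$skip) d_enc else 0, cfg)
    main <- list(cb = cb, b1 = b1, b2 = b2, proj = proj, attn = attn,
                 pl = pl, dec1 = dec1, dec2 = dec2, f1 = head$f1,
                 f2 = head$f2)
    comp <- NULL
    if (name == "IED-CNN-LSTM") {
      dc <- cfg$comp_dim
      comp <- list(
        dcmp = nn_decompose(cfg$decomp_kernel),
        m1 = nn_pwdense(cfg$C, dc, act = "relu"),
        m2 = nn_pwdense(dc, dc, act = "linear"),
        sproj = nn_pwdense(cfg$C, dc, act = "linear"),
        trans = nn_transformer(dc, cfg$trans_heads, cfg$trans_ff),
        cattn = nn_dct_attention(2 * dc, cfg$L, cfg$dct_k,
                                 min(cfg$attn_reduction, 2 * dc)),
        cpool = if (cfg$pool > 1) nn_avgpool1d(cfg$pool) else NULL,
        cflat = nn_flatten(),
        cf1 = nn_dense(cfg$L %/% max(1L, cfg$pool) * 2 * dc, cfg$fc,
                       act = "relu"),
        cf2 = nn_dense(cfg$fc, cfg$n_out, act = "linear")
      )
      # zero-init the compensation output so the full model starts exactly
      # at the main structure and the branch learns only net corrections
      comp$cf2$par$W[] <- 0
      comp$cf2$par$b[] <- 0
    }
    g$main <- main
    g$comp <- comp
    comp <- Filter(Negate(is.null), comp)
    if (!length(comp)) comp <- NULL
    g$layers <- c(cb, list(b1, b2, proj), if (!is.null(attn)) list(attn),
                  list(dec1, dec2, head$f1, head$f2),
                  if (!is.null(comp)) unname(comp))
    w3 <- cfg$conv[3]
    g$fwd <- function(x) {
      ec <- .seq_fwd(cb, x)
      er <- b2$fwd(b1$fwd(x))
      fused <- array(0, c(dim(x)[1], cfg$L, w3 + 2 * H))
      fused[, , seq_len(w3)] <- ec
      fused[, , w3 + seq_len(2 * H)] <- er
      p <- proj$fwd(fused)
      a <- if (!is.null(attn)) attn$fwd(p) else p
      if (!is.null(pl)) a <- pl$fwd(a)
      dvec <- dec2$fwd(dec1$fwd(a))
      if (cfg$skip) dvec <- cbind(dvec, matrix(a[, dim(a)[2], ], dim(a)[1]))
      out <- head$f2$fwd(head$f1$fwd(dvec))
      if (!is.null(comp)) {
        ds <- comp$dcmp$fwd(x)
        tr <- comp$m2$fwd(comp$m1$fwd(ds$trend))
        se <- comp$trans$fwd(comp$sproj$fwd(ds$seasonal))
        cc <- array(0, c(dim(x)[1], cfg$L, 2 * cfg$comp_dim))
        cc[, , seq_len(cfg$comp_dim)] <- tr
        cc[, , cfg$comp_dim + seq_len(cfg$comp_dim)] <- se
        ca <- comp$cattn$fwd(cc)
        if (!is.null(comp$cpool)) ca <- comp$cpool$fwd(ca)
        cv <- comp$cf2$fwd(comp$cf1$fwd(comp$cflat$fwd(ca)))
        out <- out + cv
      }
      out
    }
    g$bwd <- function(dy) {
      dvec_g <- head$f1$bwd(head$f2$bwd(dy))
      da <- dec1$bwd(dec2$bwd(dvec_g[, seq_len(H), drop = FALSE]))
      if (cfg$skip) {
        Lp <- dim(da)[2]
        da[, Lp, ] <- da[, Lp, ] + dvec_g[, H + seq_len(d_enc)]
      }
      if (!is.null(pl)) da <- pl$bwd(da)
      dp <- if (!is.null(attn)) attn$bwd(da) else da
      dfused <- proj$bwd(dp)
      dec_c <- dfused[, , seq_len(w3), drop = FALSE]
      dec_r <- dfused[, , w3 + seq_len(2 * H), drop = FALSE]
      dx <- .seq_bwd(cb, dec_c) + b1$bwd(b2$bwd(dec_r))
      if (!is.null(comp)) {
        dca <- comp$cflat$bwd(comp$cf1$bwd(comp$cf2$bwd(dy)))
        if (!is.null(comp$cpool)) dca <- comp$cpool$bwd(dca)
        dcc <- comp$cattn$bwd(dca)
        dtr <- dcc[, , seq_len(cfg$comp_dim), drop = FALSE]
        dse <- dcc[, , cfg$comp_dim + seq_len(cfg$comp_dim), drop = FALSE]
        d_trend <- comp$m1$bwd(comp$m2$bwd(dtr))
        d_seas <- comp$sproj$bwd(comp$trans$bwd(dse))
        dx <- dx + comp$dcmp$bwd(d_trend, d_seas)
      }
      dx
    }
  }
  class(g) <- "enose_nn_graph"
  g
}

#' Number of trainable parameters of a model graph
#' @param graph an `enose_nn_graph`.
#' @export
n_parameters <- function(graph) .n_params(graph$layers)

#' Train a deep model
#'
#' Minimizes mean squared error with Adam over shuffled mini-batches.
#' Inputs are expected normalized (see [fit_enose()] for the high-level
#' interface that handles scaling). Deterministic for a fixed seed under
#' single-threaded BLAS.
#'
#' @param graph an `enose_nn_graph` from [build_model()] (or an
#'   `enose_model_config`, which is built first).
#' @param x (N, L, C) input array.
#' @param y (N, 8) target matrix.
#' @param cfg overrides `graph$cfg` if supplied.
#' @param verbose print per-epoch loss.
#' @return object of class `enose_net`: `graph`, `config`, `history`
#'   (per-epoch mean training loss).
#' @export
train_model <- function(graph, x, y, cfg = NULL, verbose = FALSE) {
  if (inherits(graph, "enose_model_config")) graph <- build_model(graph)
  cfg <- cfg %||% graph$cfg
  N <- dim(x)[1]
  stopifnot(nrow(y) == N)
  set.seed(cfg$seed + 1L)
  history <- numeric(cfg$epochs)
  t_step <- 0L
  avg_from <- if ((cfg$avg_tail %||% 0) > 0) {
    max(1L, ceiling((1 - cfg$avg_tail) * cfg$epochs) + 1L)
  } else cfg$epochs + 1L
  avg_acc <- NULL
  n_avg <- 0L
  for (ep in seq_len(cfg$epochs)) {
    # cosine learning-rate decay over the epoch budget
    lr_ep <- cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
    idx <- sample.int(N)
    losses <- c()
    for (b0 in seq(1, N, by = cfg$batch)) {
      bi <- idx[b0:min(b0 + cfg$batch - 1, N)]
      xb <- x[bi, , , drop = FALSE]
      if ((cfg$augment %||% 0) > 0) {
        xb <- xb + rnorm(length(xb), 0, cfg$augment)
      }
      yb <- y[bi, , drop = FALSE]
      pred <- graph$fwd(xb)
      err <- pred - yb
      loss <- mean(err * err)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", ep,
             " (lr too high or inputs unscaled?)")
      }
      losses <- c(losses, loss)
      graph$bwd(2 * err / length(err))
      if (is.finite(cfg$clip %||% Inf)) .clip_grads(graph$layers, cfg$clip)
      t_step <- t_step + 1L
      .adam_step(graph$layers, lr_ep, t_step,
                 weight_decay = cfg$weight_decay %||% 0)
    }
    history[ep] <- mean(losses)
    if (ep >= avg_from) {
      ps <- .get_params(graph$layers)
      avg_acc <- if (is.null(avg_acc)) ps else {
        mapply(function(a, p) mapply(`+`, a, p, SIMPLIFY = FALSE),
               avg_acc, ps, SIMPLIFY = FALSE)
      }
      n_avg <- n_avg + 1L
    }
    if (verbose) message(sprintf("epoch %3d  mse %.5f", ep, history[ep]))
  }
  if (n_avg > 1L) {
    .set_params(graph$layers,
                lapply(avg_acc, function(l) lapply(l, `/`, n_avg)))
  }
  structure(list(graph = graph, config = cfg, history = history),
            class = "enose_net")
}

# batched forward pass without gradient bookkeeping cost
.predict_graph <- function(graph, x, batch = 64) {
  N <- dim(x)[1]
  out <- NULL
  for (b0 in seq(1, N, by = batch)) {
    bi <- b0:min(b0 + batch - 1, N)
    out <- rbind(out, graph$fwd(x[bi, , , drop = FALSE]))
  }
  out
}

#' Fit a deep concentration regressor on preprocessed windows
#'
#' High-level fitting interface: scales inputs and targets by min-max on the
#' training windows, builds the requested architecture and trains it.
#' Predictions are returned in ppm.
#'
#' @param windows list of `enose_window` training samples.
#' @param model model name (see [model_config()]).
#' @param channels channel ids used as model input.
#' @param ... overrides passed to [model_config()].
#' @param verbose print training progress.
#' @return `enose_net` with scalers attached; supports [predict()],
#'   [residuals()], [coef()], `print()`, `summary()` and `plot()`.
#' @export
fit_enose <- function(windows, model = "IED-CNN-LSTM", channels = NULL,
                      verbose = FALSE, ...) {
  ar <- windows_to_arrays(windows, channels)
  L <- dim(ar$x)[2]; C <- dim(ar$x)[3]
  cfg <- model_config(name = model, L = L, C = C, ...)
  sx <- fit_scaler(matrix(ar$x, ncol = C))
  sy <- fit_scaler(ar$y)
  xs <- ar$x
  for (j in seq_len(C)) {
    rng <- sx$max[j] - sx$min[j]
    xs[, , j] <- (xs[, , j] - sx$min[j]) / (if (rng == 0) 1 else rng)
  }
  ys <- apply_scaler(sy, ar$y)
  fit <- train_model(build_model(cfg), xs, ys, verbose = verbose)
  fit$scaler_x <- sx
  fit$scaler_y <- sy
  fit$channels <- dimnames(ar$x)[[3]]
  fit$train_y <- ar$y
  fit$train_fitted <- invert_scaler(sy, .predict_graph(fit$graph, xs))
  fit
}

#' @export
predict.enose_net <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.array(newdata)) {
    newdata <- windows_to_arrays(newdata, object$channels)$x
  }
  if (is.null(object$scaler_x)) {
    return(.predict_graph(object$graph, newdata))
  }
  C <- dim(newdata)[3]
  for (j in seq_len(C)) {
    rng <- object$scaler_x$max[j] - object$scaler_x$min[j]
    newdata[, , j] <- (newdata[, , j] - object$scaler_x$min[j]) /
      (if (rng == 0) 1 else rng)
  }
  pred <- .predict_graph(object$graph, newdata)
  colnames(pred) <- GAS_NAMES
  invert_scaler(object$scaler_y, pred)
}

#' @export
print.enose_net <- function(x, ...) {
  cat("<enose_net> ", x$config$name, ": L=", x$config$L, ", C=", x$config$C,
      ", ", format(n_parameters(x$graph), big.mark = ","),
      " parameters; final training MSE ",
      signif(tail(x$history, 1), 4), " (normalized)\n", sep = "")
  invisible(x)
}

#' @export
summary.enose_net <- function(object, ...) {
  cat("Model:", object$config$name, "\n")
  cat("Input:", object$config$L, "time steps x", object$config$C, "channels\n")
  cat("Parameters:", n_parameters(object$graph), "\n")
  cat("Epochs:", object$config$epochs, " batch:", object$config$batch,
      " lr:", object$config$lr, "\n")
  cat("Training loss (normalized MSE): first", signif(object$history[1], 4),
      "-> last", signif(tail(object$history, 1), 4), "\n")
  if (!is.null(object$train_fitted)) {
    m <- compute_metrics(object$train_y, object$train_fitted)
    cat(sprintf("Training fit (ppm): RMSE %.3f  R2 %.3f  CORR %.3f\n",
                m$pooled["rmse"], m$pooled["r2"], m$pooled["corr"]))
  }
  invisible(object)
}

#' @export
coef.enose_net <- function(object, ...) .get_params(object$graph$layers)

#' @export
residuals.enose_net <- function(object, ...) {
  if (is.null(object$train_fitted)) stop("no stored training fit")
  object$train_y - object$train_fitted
}

#' @export
plot.enose_net <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "l", xlab = "epoch",
       ylab = "training MSE (normalized)",
       main = paste(x$config$name, "training loss"), ...)
  invisible(x)
}
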