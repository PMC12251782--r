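# Minimal neural-network engine: layer constructors with hand-derived
# backpropagation, an Adam optimizer, and tensor reshape helpers.
#
# Conventions: a batch of sequence data is an array (B, L, C); flat
# activations are matrices (B, F). Each layer is an environment with
# `par` / `grad` (named lists of arrays), `fwd(x)` and `bwd(dy)` closures,
# and optionally `sub` (child layers). All randomness goes through R's RNG
# so fits are reproducible under set.seed().

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

.new_layer <- function(par = list(), sub = NULL) {
  e <- new.env(parent = emptyenv())
  e$par <- par
  e$grad <- lapply(par, function(p) array(0, dim = dim(p) %||% length(p)))
  e$sub <- sub
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten (B,L,C) -> (B*L, C); first two dims are contiguous so a plain
# dim<- is a view-free relabel
.as2d <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
.as3d <- function(x, B, L) { dim(x) <- c(B, L, ncol(x)); x }

.act_fwd <- function(a, act) {
  switch(act,
    linear = a,
    relu = pmax(a, 0),
    sigmoid = 1 / (1 + exp(-a)),
    tanh = tanh(a),
    stop("unknown activation: ", act))
}

.act_bwd <- function(dy, a, y, act) {
  switch(act,
    linear = dy,
    relu = dy * (a > 0),
    sigmoid = dy * y * (1 - y),
    tanh = dy * (1 - y * y))
}

# ---- dense ------------------------------------------------------------

nn_dense <- function(n_in, n_out, act = "linear") {
  l <- .new_layer(list(W = .glorot(n_in, n_out), b = numeric(n_out)))
  l$fwd <- function(x) {
    a <- x %*% l$par$W
    a <- sweep(a, 2, l$par$b, `+`)
    y <- .act_fwd(a, act)
    l$cache <- list(x = x, a = a, y = y)
    y
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    da <- .act_bwd(dy, cc$a, cc$y, act)
    l$grad$W <- crossprod(cc$x, da)
    l$grad$b <- colSums(da)
    da %*% t(l$par$W)
  }
  l
}

# position-wise dense over (B,L,C)
nn_pwdense <- function(n_in, n_out, act = "linear") {
  l <- nn_dense(n_in, n_out, act)
  fwd2 <- l$fwd; bwd2 <- l$bwd
  l$fwd <- function(x) {
    d <- dim(x)
    .as3d(fwd2(.as2d(x)), d[1], d[2])
  }
  l$bwd <- function(dy) {
    d <- dim(dy)
    .as3d(bwd2(.as2d(dy)), d[1], d[2])
  }
  l
}

# elementwise activation as a standalone layer
nn_act <- function(act) {
  l <- .new_layer()
  l$fwd <- function(x) {
    y <- .act_fwd(x, act)
    l$cache <- list(a = x, y = y)
    y
  }
  l$bwd <- function(dy) .act_bwd(dy, l$cache$a, l$cache$y, act)
  l
}

# ---- 1-D convolution (same padding, odd kernel) -----------------------

nn_conv1d <- function(c_in, c_out, k = 3, act = "linear") {
  stopifnot(k %% 2 == 1)
  l <- .new_layer(list(W = .glorot(k * c_in, c_out, c(k * c_in, c_out)),
                       b = numeric(c_out)))
  p <- (k - 1) / 2
  l$fwd <- function(x) {
    d <- dim(x); B <- d[1]; L <- d[2]
    if (p > 0) {
      xp <- array(0, c(B, L + 2 * p, c_in))
      xp[, p + seq_len(L), ] <- x
    } else xp <- x
    cols <- array(0, c(B, L, k * c_in))
    for (j in seq_len(k)) {
      cols[, , ((j - 1) * c_in + 1):(j * c_in)] <- xp[, j:(j + L - 1), , drop = FALSE]
    }
    cols2 <- .as2d(cols)
    a <- sweep(cols2 %*% l$par$W, 2, l$par$b, `+`)
    y <- .act_fwd(a, act)
    l$cache <- list(cols2 = cols2, a = a, y = y, B = B, L = L)
    .as3d(y, B, L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    B <- cc$B; L <- cc$L
    da <- .act_bwd(.as2d(dy), cc$a, cc$y, act)
    l$grad$W <- crossprod(cc$cols2, da)
    l$grad$b <- colSums(da)
    dcols <- .as3d(da %*% t(l$par$W), B, L)  # (B, L, k*c_in)
    dxp <- array(0, c(B, L + 2 * p, c_in))
    for (j in seq_len(k)) {
      dxp[, j:(j + L - 1), ] <- dxp[, j:(j + L - 1), , drop = FALSE] +
        dcols[, , ((j - 1) * c_in + 1):(j * c_in), drop = FALSE]
    }
    if (p > 0) dxp[, p + seq_len(L), , drop = FALSE] else dxp
  }
  l
}

# ---- layer normalization over the feature (last) axis -----------------

nn_layernorm <- function(C, eps = 1e-5) {
  l <- .new_layer(list(g = rep(1, C), b = numeric(C)))
  l$fwd <- function(x) {
    d3 <- length(dim(x)) == 3
    d <- dim(x)
    x2 <- if (d3) .as2d(x) else x
    mu <- rowMeans(x2)
    xc <- x2 - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    y <- sweep(sweep(xhat, 2, l$par$g, `*`), 2, l$par$b, `+`)
    l$cache <- list(xhat = xhat, inv = inv, d3 = d3, d = d)
    if (d3) .as3d(y, d[1], d[2]) else y
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    dy2 <- if (cc$d3) .as2d(dy) else dy
    l$grad$g <- colSums(dy2 * cc$xhat)
    l$grad$b <- colSums(dy2)
    dxhat <- sweep(dy2, 2, l$par$g, `*`)
    dx <- cc$inv * (dxhat - rowMeans(dxhat) -
                      cc$xhat * rowMeans(dxhat * cc$xhat))
    if (cc$d3) .as3d(dx, cc$d[1], cc$d[2]) else dx
  }
  l
}

# ---- LSTM (uni- or reversed-direction), C++ kernels -------------------

# orthogonal H x H block per gate (stabilizes recurrent training)
.orth_init <- function(H, n_blocks = 4) {
  do.call(cbind, lapply(seq_len(n_blocks), function(i) {
    qr.Q(qr(matrix(rnorm(H * H), H, H)))
  }))
}

nn_lstm <- function(n_in, H, return = c("seq", "last"), reverse = FALSE) {
  return <- match.arg(return)
  l <- .new_layer(list(W = .glorot(n_in, 4 * H, c(n_in, 4 * H)),
                       U = .orth_init(H),
                       b = numeric(4 * H)))
  l$par$b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  l$fwd <- function(x) {
    d <- dim(x); B <- d[1]; L <- d[2]
    if (reverse) x <- x[, L:1, , drop = FALSE]
    xc <- aperm(x, c(1, 3, 2))  # (B, C, T)
    res <- lstm_cpp_forward(xc, l$par$W, l$par$U, l$par$b)
    l$cache <- list(xc = xc, res = res, B = B, L = L)
    if (return == "seq") {
      out <- aperm(res$H, c(1, 3, 2))  # (B, T, H) -> but res$H is (B,H,T)
      if (reverse) out <- out[, L:1, , drop = FALSE]
      out
    } else {
      matrix(res$H[, , L], d[1], H)
    }
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    B <- cc$B; L <- cc$L
    if (return == "seq") {
      if (reverse) dy <- dy[, L:1, , drop = FALSE]
      dH <- aperm(dy, c(1, 3, 2))
    } else {
      dH <- array(0, dim = dim(cc$res$H))
      dH[, , L] <- dy
    }
    back <- lstm_cpp_backward(dH, cc$xc, cc$res$H, cc$res$C, cc$res$G,
                              l$par$W, l$par$U)
    l$grad$W <- back$dW
    l$grad$U <- back$dU
    l$grad$b <- as.numeric(back$db)
    dx <- aperm(back$dX, c(1, 3, 2))
    if (reverse) dx <- dx[, L:1, , drop = FALSE]
    dx
  }
  l
}

# bidirectional LSTM: forward + reversed passes concatenated on features
nn_bilstm <- function(n_in, H, return = c("seq", "last")) {
  return <- match.arg(return)
  fw <- nn_lstm(n_in, H, "seq", reverse = FALSE)
  bw <- nn_lstm(n_in, H, "seq", reverse = TRUE)
  l <- .new_layer(sub = list(fw = fw, bw = bw))
  l$fwd <- function(x) {
    d <- dim(x); L <- d[2]
    yf <- fw$fwd(x)
    yb <- bw$fwd(x)
    l$cache <- list(B = d[1], L = L, H = dim(yf)[3])
    if (return == "seq") {
      out <- array(0, c(d[1], L, 2 * dim(yf)[3]))
      out[, , seq_len(dim(yf)[3])] <- yf
      out[, , dim(yf)[3] + seq_len(dim(yf)[3])] <- yb
      out
    } else {
      # state after reading the full sequence in each direction
      cbind(matrix(yf[, L, ], d[1]), matrix(yb[, 1, ], d[1]))
    }
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    H <- cc$H
    if (return == "seq") {
      dx <- fw$bwd(dy[, , seq_len(H), drop = FALSE]) +
        bw$bwd(dy[, , H + seq_len(H), drop = FALSE])
    } else {
      dyf <- array(0, c(cc$B, cc$L, H)); dyf[, cc$L, ] <- dy[, seq_len(H)]
      dyb <- array(0, c(cc$B, cc$L, H)); dyb[, 1, ] <- dy[, H + seq_len(H)]
      dx <- fw$bwd(dyf) + bw$bwd(dyb)
    }
    dx
  }
  l
}

# ---- DCT channel attention --------------------------------------------
# Per-channel descriptor = sum of magnitudes of the first dct_k orthonormal
# DCT-II coefficients of that channel's length-L sequence; a two-layer
# bottleneck + sigmoid turns descriptors into per-channel gates in (0,1).

nn_dct_attention <- function(C, L, dct_k = 16, reduction = 4) {
  if (reduction > C) stop("reduction must be <= channel count")
  dct_k <- min(dct_k, L)
  Cr <- max(1L, floor(C / reduction))
  l <- .new_layer(list(W1 = .glorot(C, Cr), b1 = numeric(Cr),
                       W2 = .glorot(Cr, C), b2 = numeric(C)))
  D <- dct_basis(L)[seq_len(dct_k), , drop = FALSE]
  l$fwd <- function(x) {
    d <- dim(x); B <- d[1]
    xm <- aperm(x, c(2, 1, 3))          # (L, B, C)
    dim(xm) <- c(L, B * C)
    coef <- D %*% xm                     # (K, B*C)
    z <- matrix(colSums(abs(coef)), B, C)
    h1a <- sweep(z %*% l$par$W1, 2, l$par$b1, `+`)
    h1 <- pmax(h1a, 0)
    a2 <- sweep(h1 %*% l$par$W2, 2, l$par$b2, `+`)
    g <- 1 / (1 + exp(-a2))
    g3 <- aperm(array(g, c(B, C, d[2])), c(1, 3, 2))
    y <- x * g3
    l$cache <- list(x = x, sgn = sign(coef), z = z, h1a = h1a, h1 = h1,
                    g = g, g3 = g3, B = B)
    y
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    B <- cc$B
    # gate path
    pg <- dy * cc$x
    pg <- aperm(pg, c(2, 1, 3)); dim(pg) <- c(L, B * C)
    dg <- matrix(colSums(pg), B, C)
    da2 <- dg * cc$g * (1 - cc$g)
    l$grad$W2 <- crossprod(cc$h1, da2)
    l$grad$b2 <- colSums(da2)
    dh1 <- (da2 %*% t(l$par$W2)) * (cc$h1a > 0)
    l$grad$W1 <- crossprod(cc$z, dh1)
    l$grad$b1 <- colSums(dh1)
    dz <- dh1 %*% t(l$par$W1)            # (B, C)
    # descriptor path back to the input
    sc <- cc$sgn * rep(as.vector(dz), each = nrow(cc$sgn))
    dx2 <- crossprod(D, sc)              # (L, B*C)
    dim(dx2) <- c(L, B, C)
    dx2 <- aperm(dx2, c(2, 1, 3))
    dy * cc$g3 + dx2
  }
  l
}

# ---- temporal average pooling -----------------------------------------

# non-overlapping mean pooling along the L axis by an integer factor
nn_avgpool1d <- function(factor) {
  l <- .new_layer()
  l$fwd <- function(x) {
    d <- dim(x)
    stopifnot(d[2] %% factor == 0)
    l$cache <- d
    Lp <- d[2] / factor
    xm <- aperm(x, c(2, 1, 3))
    dim(xm) <- c(factor, Lp * d[1] * d[3])
    y <- colMeans(xm)
    dim(y) <- c(Lp, d[1], d[3])
    aperm(y, c(2, 1, 3))
  }
  l$bwd <- function(dy) {
    d <- l$cache
    Lp <- d[2] / factor
    g <- aperm(dy, c(2, 1, 3)) / factor
    dim(g) <- c(1, Lp * d[1] * d[3])
    g <- g[rep(1, factor), , drop = FALSE]
    dim(g) <- c(d[2], d[1], d[3])
    aperm(g, c(2, 1, 3))
  }
  l
}

# ---- flatten -----------------------------------------------------------

nn_flatten <- function() {
  l <- .new_layer()
  l$fwd <- function(x) {
    d <- dim(x)
    l$cache <- d
    dim(x) <- c(d[1], d[2] * d[3])
    x
  }
  l$bwd <- function(dy) {
    dim(dy) <- l$cache
    dy
  }
  l
}

# ---- transformer encoder layer (pre-LN, zero-init residual outputs) ---
# Pre-LN with the attention output projection and the second FFN weight
# zero-initialized: the layer starts as the identity and both residual
# branches grow from zero, which keeps training stable at the shared
# learning rates used across the model roster.

nn_transformer <- function(d_model, heads = 4, d_ff = 2 * d_model) {
  if (d_model %% heads != 0) stop("d_model must be divisible by heads")
  dh <- d_model / heads
  ln1 <- nn_layernorm(d_model)
  ln2 <- nn_layernorm(d_model)
  l <- .new_layer(list(
    Wq = .glorot(d_model, d_model), bq = numeric(d_model),
    Wk = .glorot(d_model, d_model), bk = numeric(d_model),
    Wv = .glorot(d_model, d_model), bv = numeric(d_model),
    Wo = matrix(0, d_model, d_model), bo = numeric(d_model),
    W1 = .glorot(d_model, d_ff), b1 = numeric(d_ff),
    W2 = matrix(0, d_ff, d_model), b2 = numeric(d_model)
  ), sub = list(ln1 = ln1, ln2 = ln2))
  proj <- function(x2, W, b) sweep(x2 %*% W, 2, b, `+`)
  l$fwd <- function(x) {
    d <- dim(x); B <- d[1]; L <- d[2]
    x2 <- .as2d(x)
    n1 <- ln1$fwd(x2)
    Q <- proj(n1, l$par$Wq, l$par$bq)
    K <- proj(n1, l$par$Wk, l$par$bk)
    V <- proj(n1, l$par$Wv, l$par$bv)
    Q3 <- .as3d(Q, B, L); K3 <- .as3d(K, B, L); V3 <- .as3d(V, B, L)
    O3 <- array(0, c(B, L, d_model))
    A <- vector("list", B)
    for (b in seq_len(B)) {
      Ab <- vector("list", heads)
      for (h in seq_len(heads)) {
        idx <- ((h - 1) * dh + 1):(h * dh)
        Qb <- matrix(Q3[b, , idx], L); Kb <- matrix(K3[b, , idx], L)
        S <- Qb %*% t(Kb) / sqrt(dh)
        S <- exp(S - apply(S, 1, max))
        S <- S / rowSums(S)
        Ab[[h]] <- S
        O3[b, , idx] <- S %*% matrix(V3[b, , idx], L)
      }
      A[[b]] <- Ab
    }
    O2 <- .as2d(O3)
    res1 <- x2 + proj(O2, l$par$Wo, l$par$bo)
    n2 <- ln2$fwd(res1)
    h1a <- proj(n2, l$par$W1, l$par$b1)
    h1 <- pmax(h1a, 0)
    out <- res1 + proj(h1, l$par$W2, l$par$b2)
    l$cache <- list(x2 = x2, n1 = n1, Q3 = Q3, K3 = K3, V3 = V3, A = A,
                    O2 = O2, n2 = n2, h1a = h1a, h1 = h1, B = B, L = L)
    .as3d(out, B, L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    B <- cc$B; L <- cc$L
    dout <- .as2d(dy)
    # FFN residual branch
    dffn <- dout
    l$grad$W2 <- crossprod(cc$h1, dffn)
    l$grad$b2 <- colSums(dffn)
    dh1 <- (dffn %*% t(l$par$W2)) * (cc$h1a > 0)
    l$grad$W1 <- crossprod(cc$n2, dh1)
    l$grad$b1 <- colSums(dh1)
    dres1 <- dout + ln2$bwd(dh1 %*% t(l$par$W1))
    # attention residual branch
    dattn <- dres1
    l$grad$Wo <- crossprod(cc$O2, dattn)
    l$grad$bo <- colSums(dattn)
    dO3 <- .as3d(dattn %*% t(l$par$Wo), B, L)
    dQ3 <- array(0, c(B, L, d_model))
    dK3 <- array(0, c(B, L, d_model))
    dV3 <- array(0, c(B, L, d_model))
    for (b in seq_len(B)) {
      for (h in seq_len(heads)) {
        idx <- ((h - 1) * dh + 1):(h * dh)
        S <- cc$A[[b]][[h]]
        dOb <- matrix(dO3[b, , idx], L)
        Vb <- matrix(cc$V3[b, , idx], L)
        Qb <- matrix(cc$Q3[b, , idx], L)
        Kb <- matrix(cc$K3[b, , idx], L)
        dS <- dOb %*% t(Vb)
        dV3[b, , idx] <- crossprod(S, dOb)
        dZ <- S * (dS - rowSums(dS * S))
        dQ3[b, , idx] <- dZ %*% Kb / sqrt(dh)
        dK3[b, , idx] <- crossprod(dZ, Qb) / sqrt(dh)
      }
    }
    dQ <- .as2d(dQ3); dK <- .as2d(dK3); dV <- .as2d(dV3)
    l$grad$Wq <- crossprod(cc$n1, dQ); l$grad$bq <- colSums(dQ)
    l$grad$Wk <- crossprod(cc$n1, dK); l$grad$bk <- colSums(dK)
    l$grad$Wv <- crossprod(cc$n1, dV); l$grad$bv <- colSums(dV)
    dn1 <- dQ %*% t(l$par$Wq) + dK %*% t(l$par$Wk) + dV %*% t(l$par$Wv)
    .as3d(dres1 + ln1$bwd(dn1), B, L)
  }
  l
}

# ---- series decomposition (moving average trend + seasonal residual) --

# centered moving average with edge replication, over the L axis of a
# (B, L, C) array (or an L x C matrix); returns trend + seasonal with
# exact additive reconstruction
.moving_avg <- function(xm, h) {
  # xm: (L, M) matrix; returns (L, M) trend. Centered window via a single
  # C-level convolution on the edge-replicated matrix.
  L <- nrow(xm)
  if (h == 0) return(xm)
  w <- 2 * h + 1
  xp <- rbind(matrix(rep(xm[1, ], each = h), h), xm,
              matrix(rep(xm[L, ], each = h), h))
  f <- stats::filter(xp, rep(1 / w, w), sides = 2)
  matrix(f[h + seq_len(L), ], L)
}

# adjoint of .moving_avg (for backprop): a trailing-window sum over the
# zero-extended gradient, then edge-fold of the replicated padding
.moving_avg_adj <- function(gm, h) {
  L <- nrow(gm)
  if (h == 0) return(gm)
  w <- 2 * h + 1
  M <- ncol(gm)
  gpad <- rbind(matrix(0, 2 * h, M), gm, matrix(0, 2 * h, M))
  f <- stats::filter(gpad, rep(1 / w, w), sides = 1)
  gp <- matrix(f[2 * h + seq_len(L + 2 * h), ], L + 2 * h)
  out <- gp[h + seq_len(L), , drop = FALSE]
  out[1, ] <- out[1, ] + colSums(gp[seq_len(h), , drop = FALSE])
  out[L, ] <- out[L, ] + colSums(gp[L + h + seq_len(h), , drop = FALSE])
  out
}

#' Trend / seasonal decomposition of a window
#'
#' The trend is a centered moving average (odd kernel, edges replicated);
#' the seasonal component is the residual, so `trend + seasonal`
#' reconstructs the input exactly.
#'
#' @param window L x C numeric matrix (or a (B, L, C) array).
#' @param kernel odd moving-average width, `<=` L.
#' @return list with `trend` and `seasonal`, same shape as the input.
#' @export
decompose_series <- function(window, kernel = 25) {
  if (kernel %% 2 != 1) stop("kernel must be odd")
  h <- (kernel - 1) / 2
  if (is.matrix(window)) {
    if (kernel > nrow(window)) stop("kernel must be <= window length")
    trend <- .moving_avg(window, h)
    dimnames(trend) <- dimnames(window)
    return(list(trend = trend, seasonal = window - trend))
  }
  d <- dim(window)
  stopifnot(length(d) == 3)
  if (kernel > d[2]) stop("kernel must be <= window length")
  xm <- aperm(window, c(2, 1, 3)); dim(xm) <- c(d[2], d[1] * d[3])
  tr <- .moving_avg(xm, h)
  dim(tr) <- c(d[2], d[1], d[3])
  trend <- aperm(tr, c(2, 1, 3))
  list(trend = trend, seasonal = window - trend)
}

# decomposition as a layer emitting list(trend, seasonal); bwd takes
# list(d_trend, d_seasonal)
nn_decompose <- function(kernel) {
  h <- (kernel - 1) / 2
  l <- .new_layer()
  l$fwd <- function(x) {
    l$cache <- dim(x)
    decompose_series(x, kernel)
  }
  l$bwd <- function(d_trend, d_seasonal) {
    d <- l$cache
    gm <- d_trend - d_seasonal
    gm <- aperm(gm, c(2, 1, 3)); dim(gm) <- c(d[2], d[1] * d[3])
    adj <- .moving_avg_adj(gm, h)
    dim(adj) <- c(d[2], d[1], d[3])
    d_seasonal + aperm(adj, c(2, 1, 3))
  }
  l
}

# ---- parameter plumbing ------------------------------------------------

.collect_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (!is.null(l$sub)) out <- c(out, .collect_layers(l$sub))
    if (length(l$par)) out <- c(out, list(l))
  }
  out
}

.n_params <- function(layers) {
  sum(vapply(.collect_layers(layers),
             function(l) sum(vapply(l$par, length, numeric(1))), numeric(1)))
}

# global-norm gradient clipping (in place); no-op when the norm is small
.clip_grads <- function(layers, max_norm) {
  ls <- .collect_layers(layers)
  tot <- 0
  for (l in ls) for (g in l$grad) tot <- tot + sum(g * g)
  tot <- sqrt(tot)
  if (is.finite(tot) && tot > max_norm) {
    sc <- max_norm / tot
    for (l in ls) l$grad <- lapply(l$grad, `*`, sc)
  }
  invisible(tot)
}

# Adam update over every parameterized layer (in place); weight_decay is
# decoupled (AdamW) and skipped for biases / 1-D gains
.adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  for (l in .collect_layers(layers)) {
    if (is.null(l$opt)) {
      l$opt <- list(m = lapply(l$par, function(p) p * 0),
                    v = lapply(l$par, function(p) p * 0))
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g * g
      mhat <- l$opt$m[[nm]] / (1 - beta1^t)
      vhat <- l$opt$v[[nm]] / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (weight_decay > 0 && !is.null(dim(l$par[[nm]]))) {
        upd <- upd + lr * weight_decay * l$par[[nm]]
      }
      l$par[[nm]] <- l$par[[nm]] - upd
    }
  }
}

# snapshot / restore parameters (for checkpointing and tests)
.get_params <- function(layers) {
  lapply(.collect_layers(layers), function(l) l$par)
}

.set_params <- function(layers, params) {
  ls <- .collect_layers(layers)
  stopifnot(length(ls) == length(params))
  for (i in seq_along(ls)) ls[[i]]$par <- params[[i]]
  invisible(NULL)
}
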