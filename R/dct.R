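# Orthonormal DCT-II / DCT-III, used by the DCT channel attention.

#' Orthonormal type-II discrete cosine transform
#'
#' Computed via an FFT of the even extension (length 2L), scaled to the
#' orthonormal convention so that Parseval's identity holds and
#' [idct_transform()] is the exact inverse.
#'
#' @param x numeric vector (length >= 1).
#' @return numeric vector of DCT-II coefficients, same length.
#' @export
dct_transform <- function(x) {
  L <- length(x)
  if (L == 0) stop("empty input")
  if (L == 1) return(x)
  # even extension trick: X_k = Re( e^{-i pi k / (2L)} * FFT([x, rev(x)])_k )
  X <- fft(c(x, rev(x)))
  k <- 0:(L - 1)
  coef <- Re(exp(-1i * pi * k / (2 * L)) * X[1:L]) / 2
  # orthonormal scaling
  coef <- coef * sqrt(2 / L)
  coef[1] <- coef[1] / sqrt(2)
  coef
}

#' @rdname dct_transform
#' @param coef DCT-II coefficients.
#' @export
idct_transform <- function(coef) {
  L <- length(coef)
  if (L == 0) stop("empty input")
  if (L == 1) return(coef)
  # inverse = orthonormal DCT-III, via the transposed basis (O(L^2) matrix
  # product; L <= a few hundred in this package)
  D <- dct_basis(L)
  as.numeric(crossprod(D, coef))
}

#' Orthonormal DCT-II basis matrix
#'
#' Row `k` holds the k-th orthonormal DCT-II basis vector, so `D %*% x` is
#' [dct_transform()] of `x`.
#'
#' @param L transform length.
#' @return L x L matrix.
#' @export
dct_basis <- function(L) {
  n <- 0:(L - 1)
  D <- sqrt(2 / L) * cos(pi * outer(0:(L - 1), (n + 0.5)) / L)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}
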