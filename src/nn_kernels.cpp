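// LSTM forward / backward kernels. Activations are passed as cubes with
// dimensions (batch, features, time); gate order in the 4H blocks is
// input, forget, cell-candidate, output. Gate math is done in place on the
// pre-activation matrix to keep per-timestep allocations low.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List lstm_cpp_forward(const arma::cube& x, const arma::mat& W,
                            const arma::mat& U, const arma::rowvec& b) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  cube Hs(B, H, T), Cs(B, H, T), Gs(B, 4 * H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat& G = Gs.slice(t);
    G = x.slice(t) * W + h * U;
    G.each_row() += b;
    // sigmoid on i, f, o blocks; tanh on g block (in place)
    G.cols(0, 2 * H - 1) = 1.0 / (1.0 + exp(-G.cols(0, 2 * H - 1)));
    G.cols(2 * H, 3 * H - 1) = tanh(G.cols(2 * H, 3 * H - 1));
    G.cols(3 * H, 4 * H - 1) = 1.0 / (1.0 + exp(-G.cols(3 * H, 4 * H - 1)));
    c = G.cols(H, 2 * H - 1) % c + G.cols(0, H - 1) % G.cols(2 * H, 3 * H - 1);
    h = G.cols(3 * H, 4 * H - 1) % tanh(c);
    Hs.slice(t) = h;
    Cs.slice(t) = c;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
                            Rcpp::Named("G") = Gs);
}

// [[Rcpp::export]]
Rcpp::List lstm_cpp_backward(const arma::cube& dH, const arma::cube& x,
                             const arma::cube& Hs, const arma::cube& Cs,
                             const arma::cube& Gs, const arma::mat& W,
                             const arma::mat& U) {
  const uword B = x.n_rows, I = x.n_cols, T = x.n_slices, H = U.n_rows;
  cube dX(B, I, T);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat dU(U.n_rows, U.n_cols, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  mat da(B, 4 * H), dh(B, H), dc(B, H), tc(B, H);
  const mat zero(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    dh = dH.slice(tt) + dh_next;
    const mat& G = Gs.slice(tt);
    auto gi = G.cols(0, H - 1);
    auto gf = G.cols(H, 2 * H - 1);
    auto gg = G.cols(2 * H, 3 * H - 1);
    auto go = G.cols(3 * H, 4 * H - 1);
    tc = tanh(Cs.slice(tt));
    dc = dc_next + dh % go % (1.0 - tc % tc);
    const mat& c_prev = (tt > 0) ? Cs.slice(tt - 1) : zero;
    const mat& h_prev = (tt > 0) ? Hs.slice(tt - 1) : zero;
    da.cols(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    da.cols(H, 2 * H - 1) = (dc % c_prev) % gf % (1.0 - gf);
    da.cols(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    da.cols(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    dW += x.slice(tt).t() * da;
    dU += h_prev.t() * da;
    db += sum(da, 0);
    dX.slice(tt) = da * W.t();
    dh_next = da * U.t();
    dc_next = dc % gf;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}
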