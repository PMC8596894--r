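// Minimal LSTM sequence kernels used by the context-mention encoder.
// Gate row blocks in W/U/b are ordered [input; forget; output; cell].
// A "reverse" run processes columns right-to-left but stores states at
// their original column, so H[, t] is always the state *at* token t.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline vec sigmoidv(const vec& x) {
  return 1.0 / (1.0 + exp(-x));
}

// [[Rcpp::export]]
List lstm_forward_cpp(const arma::mat& X, const arma::mat& W,
                      const arma::mat& U, const arma::vec& b,
                      bool reverse) {
  const uword T = X.n_cols;
  const uword H = U.n_cols;
  mat Hs(H, T, fill::zeros), Cs(H, T, fill::zeros);
  mat I(H, T, fill::zeros), F(H, T, fill::zeros);
  mat O(H, T, fill::zeros), G(H, T, fill::zeros);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (uword j = 0; j < T; ++j) {
    uword t = reverse ? (T - 1 - j) : j;
    vec a = W * X.col(t) + U * h + b;
    vec i = sigmoidv(a.subvec(0, H - 1));
    vec f = sigmoidv(a.subvec(H, 2 * H - 1));
    vec o = sigmoidv(a.subvec(2 * H, 3 * H - 1));
    vec g = tanh(a.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    I.col(t) = i; F.col(t) = f; O.col(t) = o; G.col(t) = g;
    Cs.col(t) = c; Hs.col(t) = h;
  }
  return List::create(_["H"] = Hs, _["C"] = Cs, _["I"] = I, _["F"] = F,
                      _["O"] = O, _["G"] = G);
}

// Backprop through time for one direction. dH holds dLoss/dH[, t] injected
// from above; returns gradients w.r.t. inputs and parameters.
// [[Rcpp::export]]
List lstm_backward_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::mat& U,
                       const arma::mat& Hs, const arma::mat& Cs,
                       const arma::mat& I, const arma::mat& F,
                       const arma::mat& O, const arma::mat& G,
                       const arma::mat& dH, bool reverse) {
  const uword T = X.n_cols;
  const uword H = U.n_cols;
  mat dX(X.n_rows, T, fill::zeros);
  mat dW(size(W), fill::zeros), dU(size(U), fill::zeros);
  vec db(4 * H, fill::zeros);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  vec onesH(H, fill::ones);
  for (uword j = 0; j < T; ++j) {
    // walk the processing order backwards
    uword idx = T - 1 - j;
    uword t = reverse ? (T - 1 - idx) : idx;
    bool has_prev = idx > 0;
    uword tprev = 0;
    if (has_prev) tprev = reverse ? (T - idx) : (idx - 1);
    vec hprev = has_prev ? vec(Hs.col(tprev)) : vec(H, fill::zeros);
    vec cprev = has_prev ? vec(Cs.col(tprev)) : vec(H, fill::zeros);
    vec i = I.col(t), f = F.col(t), o = O.col(t), g = G.col(t);
    vec tc = tanh(vec(Cs.col(t)));
    vec dh = dH.col(t) + dh_next;
    vec do_ = dh % tc;
    vec dc = dc_next + dh % o % (onesH - tc % tc);
    vec di = dc % g;
    vec dg = dc % i;
    vec df = dc % cprev;
    vec dai = di % i % (onesH - i);
    vec daf = df % f % (onesH - f);
    vec dao = do_ % o % (onesH - o);
    vec dag = dg % (onesH - g % g);
    vec da = join_cols(join_cols(dai, daf), join_cols(dao, dag));
    dW += da * X.col(t).t();
    dU += da * hprev.t();
    db += da;
    dX.col(t) = W.t() * da;
    dh_next = U.t() * da;
    dc_next = dc % f;
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU,
                      _["db"] = db);
}
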