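// LSTM forward/backward kernels for one direction over a padded batch.
//
// Layout convention: "stacked" matrices have B*T rows, where row
// (t-1)*B + b holds timestep t of batch row b (the column-major order of
// a B x T index matrix).  Masked (padding) positions zero the hidden and
// cell state, so padding never leaks into real positions in either
// direction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& Xstack, const arma::mat& maskN,
                            const arma::mat& Wx, const arma::mat& Wh,
                            const arma::vec& b, bool reverse) {
  const uword B = maskN.n_rows, T = maskN.n_cols, H = Wh.n_rows;
  mat Hstack(B * T, H), Gates(B * T, 4 * H), Cnew(B * T, H);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  const rowvec bt = b.t();
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? (T - 1 - s) : s;
    const uword r0 = t * B, r1 = t * B + B - 1;
    mat pre = Xstack.rows(r0, r1) * Wx + h * Wh;
    pre.each_row() += bt;
    mat gi = sigm(pre.cols(0, H - 1));
    mat gf = sigm(pre.cols(H, 2 * H - 1));
    mat gg = tanh(pre.cols(2 * H, 3 * H - 1));
    mat go = sigm(pre.cols(3 * H, 4 * H - 1));
    mat cn = gf % c + gi % gg;
    mat hn = go % tanh(cn);
    const vec m = maskN.col(t);
    h = hn.each_col() % m;
    c = cn.each_col() % m;
    Hstack.rows(r0, r1) = h;
    Cnew.rows(r0, r1) = cn;
    Gates.submat(r0, 0, r1, H - 1) = gi;
    Gates.submat(r0, H, r1, 2 * H - 1) = gf;
    Gates.submat(r0, 2 * H, r1, 3 * H - 1) = gg;
    Gates.submat(r0, 3 * H, r1, 4 * H - 1) = go;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hstack,
                            Rcpp::Named("gates") = Gates,
                            Rcpp::Named("cnew") = Cnew);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& Xstack, const arma::mat& maskN,
                             const arma::mat& Wx, const arma::mat& Wh,
                             const arma::mat& Hstack, const arma::mat& Gates,
                             const arma::mat& Cnew, const arma::mat& dHstack,
                             bool reverse) {
  const uword B = maskN.n_rows, T = maskN.n_cols, H = Wh.n_rows;
  mat dWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat dWh(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dXstack(B * T, Xstack.n_cols);
  mat dh_rec(B, H, fill::zeros), dc_rec(B, H, fill::zeros);
  // iterate timesteps in the reverse of the forward iteration order
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? s : (T - 1 - s);
    const uword r0 = t * B, r1 = t * B + B - 1;
    const vec m = maskN.col(t);
    const mat gi = Gates.submat(r0, 0, r1, H - 1);
    const mat gf = Gates.submat(r0, H, r1, 2 * H - 1);
    const mat gg = Gates.submat(r0, 2 * H, r1, 3 * H - 1);
    const mat go = Gates.submat(r0, 3 * H, r1, 4 * H - 1);
    const mat th = tanh(Cnew.rows(r0, r1));
    // masked states of the previous step in iteration order
    mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
    const bool has_prev = reverse ? (t + 1 < T) : (t > 0);
    if (has_prev) {
      const uword tp = reverse ? (t + 1) : (t - 1);
      const vec mp = maskN.col(tp);
      h_prev = Hstack.rows(tp * B, tp * B + B - 1);
      mat cp = Cnew.rows(tp * B, tp * B + B - 1);
      c_prev = cp.each_col() % mp;
    }
    mat dh = dHstack.rows(r0, r1) + dh_rec;
    dh.each_col() %= m;
    mat dc = dc_rec;
    dc.each_col() %= m;
    mat do_ = dh % th;
    mat dcn = dh % go % (1.0 - th % th) + dc;
    mat da = join_rows(dcn % gg % gi % (1.0 - gi),
                       dcn % c_prev % gf % (1.0 - gf),
                       dcn % gi % (1.0 - gg % gg),
                       do_ % go % (1.0 - go));
    dWx += Xstack.rows(r0, r1).t() * da;
    dWh += h_prev.t() * da;
    db += sum(da, 0);
    dh_rec = da * Wh.t();
    dc_rec = dcn % gf;
    dXstack.rows(r0, r1) = da * Wx.t();
  }
  return Rcpp::List::create(Rcpp::Named("Wx") = dWx,
                            Rcpp::Named("Wh") = dWh,
                            Rcpp::Named("b") = vec(db.t()),
                            Rcpp::Named("dX") = dXstack);
}
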