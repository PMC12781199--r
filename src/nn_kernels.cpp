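// Hot loops of the multitask GRU+conv network.
//
// Sequences travel as (B*T) x C matrices with the T time blocks stacked
// rowwise (time block t occupies rows [t*B, (t+1)*B)). The recurrent time
// loop and the convolution unroll/scatter live here; everything else stays
// in R on BLAS-backed matrix algebra.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// GRU, reset-before-multiplication variant:
//   z = sigm(x Wz + h Uz + bz); r = sigm(x Wr + h Ur + br)
//   n = tanh(x Wn + (r % h) Un + bn); h' = (1 - z) % n + z % h
// W packs [z, r, n] gates columnwise, Uzr packs [z, r], Un acts on r % h.

// [[Rcpp::export]]
Rcpp::List gru_forward_cpp(const arma::mat& x_stack, int bsz, int tlen,
                           const arma::mat& w, const arma::mat& uzr,
                           const arma::mat& un, const arma::vec& b) {
  const uword h = un.n_cols;
  mat xw = x_stack * w;
  xw.each_row() += b.t();

  mat zs(bsz * tlen, h), rs(bsz * tlen, h), ns(bsz * tlen, h),
      hs(bsz * tlen, h);
  mat hp(bsz, h, fill::zeros);

  for (int t = 0; t < tlen; ++t) {
    const uword r0 = (uword)t * bsz, r1 = r0 + bsz - 1;
    mat pre_zr = xw.submat(r0, 0, r1, 2 * h - 1) + hp * uzr;
    mat z = 1.0 / (1.0 + exp(-pre_zr.cols(0, h - 1)));
    mat r = 1.0 / (1.0 + exp(-pre_zr.cols(h, 2 * h - 1)));
    mat n = tanh(xw.submat(r0, 2 * h, r1, 3 * h - 1) + (r % hp) * un);
    hp = (1.0 - z) % n + z % hp;
    zs.rows(r0, r1) = z;
    rs.rows(r0, r1) = r;
    ns.rows(r0, r1) = n;
    hs.rows(r0, r1) = hp;
  }
  return Rcpp::List::create(
      Rcpp::Named("h_stack") = hs, Rcpp::Named("z") = zs,
      Rcpp::Named("r") = rs, Rcpp::Named("n") = ns);
}

// [[Rcpp::export]]
Rcpp::List gru_backward_cpp(const arma::mat& dh_stack,
                            const arma::mat& x_stack, const arma::mat& zs,
                            const arma::mat& rs, const arma::mat& ns,
                            const arma::mat& hs, const arma::mat& w,
                            const arma::mat& uzr, const arma::mat& un,
                            int bsz, int tlen) {
  const uword h = un.n_cols;
  mat dpre(bsz * tlen, 3 * h);
  mat hprev(bsz * tlen, h, fill::zeros);
  if (tlen > 1) {
    hprev.rows(bsz, bsz * tlen - 1) = hs.rows(0, bsz * (tlen - 1) - 1);
  }
  mat dh(bsz, h, fill::zeros);
  const mat tuzr = uzr.t();
  const mat tun = un.t();

  for (int t = tlen - 1; t >= 0; --t) {
    const uword r0 = (uword)t * bsz, r1 = r0 + bsz - 1;
    dh += dh_stack.rows(r0, r1);
    const mat z = zs.rows(r0, r1);
    const mat r = rs.rows(r0, r1);
    const mat n = ns.rows(r0, r1);
    const mat hp = hprev.rows(r0, r1);
    mat dz_pre = dh % (hp - n) % z % (1.0 - z);
    mat dn_pre = dh % (1.0 - z) % (1.0 - n % n);
    mat drh = dn_pre * tun;
    mat dr_pre = drh % hp % r % (1.0 - r);
    dh = dh % z + drh % r +
         join_rows(dz_pre, dr_pre) * tuzr;
    dpre.submat(r0, 0, r1, h - 1) = dz_pre;
    dpre.submat(r0, h, r1, 2 * h - 1) = dr_pre;
    dpre.submat(r0, 2 * h, r1, 3 * h - 1) = dn_pre;
  }
  mat rh = rs % hprev;
  mat dx = dpre * w.t();
  mat dw = x_stack.t() * dpre;
  mat duzr = hprev.t() * dpre.cols(0, 2 * h - 1);
  mat dun = rh.t() * dpre.cols(2 * h, 3 * h - 1);
  rowvec db = sum(dpre, 0);
  return Rcpp::List::create(
      Rcpp::Named("dx_stack") = dx, Rcpp::Named("dw") = dw,
      Rcpp::Named("duzr") = duzr, Rcpp::Named("dun") = dun,
      Rcpp::Named("db") = db.t());
}

// im2col for 1-D convolution with same padding, on the stacked layout:
// output (B*T) x (k*C); column block o holds the input shifted by
// (o - pad) time steps.

// [[Rcpp::export]]
arma::mat conv_unroll_cpp(const arma::mat& x_stack, int bsz, int tlen,
                          int k) {
  const int cin = x_stack.n_cols;
  const int pad = (k - 1) / 2;
  mat xcol(bsz * (uword)tlen, (uword)k * cin, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int shift = o - pad;  // source time = t + shift
    const int t_lo = std::max(0, -shift);
    const int t_hi = std::min(tlen - 1, tlen - 1 - shift);
    if (t_lo > t_hi) continue;
    xcol.submat((uword)t_lo * bsz, (uword)o * cin,
                (uword)(t_hi + 1) * bsz - 1, (uword)(o + 1) * cin - 1) =
        x_stack.rows((uword)(t_lo + shift) * bsz,
                     (uword)(t_hi + 1 + shift) * bsz - 1);
  }
  return xcol;
}

// scatter-add the im2col gradient back onto the input sequence

// [[Rcpp::export]]
arma::mat conv_scatter_cpp(const arma::mat& dxcol, int bsz, int tlen,
                           int k, int cin) {
  const int pad = (k - 1) / 2;
  mat dx(bsz * (uword)tlen, (uword)cin, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int shift = o - pad;
    const int t_lo = std::max(0, -shift);
    const int t_hi = std::min(tlen - 1, tlen - 1 - shift);
    if (t_lo > t_hi) continue;
    dx.rows((uword)(t_lo + shift) * bsz,
            (uword)(t_hi + 1 + shift) * bsz - 1) +=
        dxcol.submat((uword)t_lo * bsz, (uword)o * cin,
                     (uword)(t_hi + 1) * bsz - 1, (uword)(o + 1) * cin - 1);
  }
  return dx;
}
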