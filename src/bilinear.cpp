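// Fused kernels for the relation modules.
//
// Bilinear pairing stage: h[b, k] = u_b' A_k v_b + c[k]. Batches address
// *unique* entity instances: the entity latents and the contraction
// UA = U %*% A are computed once per unique instance, and only the cheap
// pairing reduction runs per cell. Matrices arrive transposed (columns =
// instances / cells) so every inner loop walks contiguous memory.
//
// Layout: A is wu x (H * wv) with column j * H + k (0-based) holding
// A_k[, j], so UA columns interleave the H outputs per v-coordinate.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// UAuT: (H*wv) x nu, VuT: wv x nv, iu/iv: 1-based per-cell instance index.
// Returns hT: H x B (transposed back in R).
// [[Rcpp::export]]
arma::mat pair_bil_fwd_cpp(const arma::mat& UAuT, const arma::mat& VuT,
                           const arma::ivec& iu, const arma::ivec& iv,
                           const arma::vec& c) {
  const uword B = iu.n_elem, H = c.n_elem, wv = VuT.n_rows;
  mat hT(H, B);
  for (uword b = 0; b < B; ++b) {
    const double* ua = UAuT.colptr(iu[b] - 1);
    const double* vv = VuT.colptr(iv[b] - 1);
    double* hb = hT.colptr(b);
    for (uword k = 0; k < H; ++k) hb[k] = c[k];
    for (uword j = 0; j < wv; ++j) {
      const double vj = vv[j];
      const double* uaj = ua + j * H;
      for (uword k = 0; k < H; ++k) hb[k] += uaj[k] * vj;
    }
  }
  return hT;
}

// dhT: H x B. Returns per-unique-instance gradients dUAuT ((H*wv) x nu)
// and dVuT (wv x nv), plus dc.
// [[Rcpp::export]]
Rcpp::List pair_bil_bwd_cpp(const arma::mat& dhT, const arma::mat& UAuT,
                            const arma::mat& VuT, const arma::ivec& iu,
                            const arma::ivec& iv) {
  const uword B = iu.n_elem, H = dhT.n_rows, wv = VuT.n_rows;
  mat dUAuT(UAuT.n_rows, UAuT.n_cols, fill::zeros);
  mat dVuT(VuT.n_rows, VuT.n_cols, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    const uword cu = iu[b] - 1, cv = iv[b] - 1;
    const double* ua = UAuT.colptr(cu);
    const double* vv = VuT.colptr(cv);
    const double* dhb = dhT.colptr(b);
    double* dua = dUAuT.colptr(cu);
    double* dvv = dVuT.colptr(cv);
    for (uword j = 0; j < wv; ++j) {
      const double vj = vv[j];
      const uword off = j * H;
      double acc = 0.0;
      for (uword k = 0; k < H; ++k) {
        dua[off + k] += dhb[k] * vj;
        acc += dhb[k] * ua[off + k];
      }
      dvv[j] += acc;
    }
  }
  vec dc = sum(dhT, 1);
  return Rcpp::List::create(Rcpp::Named("dUAuT") = dUAuT,
                            Rcpp::Named("dVuT") = dVuT,
                            Rcpp::Named("dc") = dc);
}

// Inner-product scoring on unique latents (linear MF limit).
// [[Rcpp::export]]
arma::vec pair_dot_cpp(const arma::mat& UuT, const arma::mat& VuT,
                       const arma::ivec& iu, const arma::ivec& iv) {
  const uword B = iu.n_elem, w = UuT.n_rows;
  vec s(B);
  for (uword b = 0; b < B; ++b) {
    const double* u = UuT.colptr(iu[b] - 1);
    const double* v = VuT.colptr(iv[b] - 1);
    double acc = 0.0;
    for (uword j = 0; j < w; ++j) acc += u[j] * v[j];
    s[b] = acc;
  }
  return s;
}

// Fused feed-forward layer: z = x W + b, optional per-row layer
// normalization (pre-activation), optional tanh.

// [[Rcpp::export]]
Rcpp::List layer_fwd_cpp(const arma::mat& x, const arma::mat& W,
                         const arma::vec& b, bool use_norm, bool tanh_act) {
  const double eps = 1e-5;
  mat z = x * W;
  z.each_row() += b.t();
  vec inv;
  if (use_norm) {
    vec m = mean(z, 1);
    z.each_col() -= m;
    inv = 1.0 / sqrt(mean(square(z), 1) + eps);
    z.each_col() %= inv;
  }
  mat a = tanh_act ? mat(tanh(z)) : z;
  return Rcpp::List::create(Rcpp::Named("a") = a, Rcpp::Named("zn") = z,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List layer_bwd_cpp(const arma::mat& dout, const arma::mat& x,
                         const arma::mat& a, const arma::mat& zn,
                         const arma::vec& inv, const arma::mat& W,
                         bool use_norm, bool tanh_act) {
  mat dzn = tanh_act ? mat(dout % (1.0 - square(a))) : dout;
  mat dz;
  if (use_norm) {
    vec r1 = mean(dzn, 1);
    vec r2 = mean(dzn % zn, 1);
    dz = dzn;
    dz.each_col() -= r1;
    mat t = zn;
    t.each_col() %= r2;
    dz -= t;
    dz.each_col() %= inv;
  } else {
    dz = dzn;
  }
  mat dW = x.t() * dz;
  rowvec db = sum(dz, 0);
  mat dx = dz * W.t();
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db.t());
}
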