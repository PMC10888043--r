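// Hot numeric kernels for the transformer layers: batched multi-head
// attention, GELU and layer norm. These mirror the pure-R reference
// implementations in R/nn_core.R exactly (tested for equality); the batch is
// stored subject-major as a (B*L) x d matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_mhab_fwd(const arma::mat& xq, const arma::mat& xk, const arma::mat& xv,
                        int Lq, int Lk, int B, int heads,
                        const arma::mat& Wq, const arma::vec& bq,
                        const arma::mat& Wk, const arma::vec& bk,
                        const arma::mat& Wv, const arma::vec& bv,
                        const arma::mat& Wo, const arma::vec& bo) {
  const int d = xq.n_cols;
  const int dk = d / heads;
  const double s = std::sqrt((double)dk);
  mat Q = xq * Wq; Q.each_row() += bq.t();
  mat K = xk * Wk; K.each_row() += bk.t();
  mat V = xv * Wv; V.each_row() += bv.t();
  mat O(B * Lq, d, fill::zeros);
  cube P(Lq, Lk, B * heads);
  for (int b = 0; b < B; ++b) {
    const int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dk;
      mat A = Q.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) *
              K.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1).t() / s;
      A.each_col() -= max(A, 1);
      A = exp(A);
      A.each_col() /= sum(A, 1);
      P.slice(b * heads + h) = A;
      O.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) =
        A * V.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
    }
  }
  mat out = O * Wo; out.each_row() += bo.t();
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("Q") = Q,
                            Rcpp::Named("K") = K, Rcpp::Named("V") = V,
                            Rcpp::Named("O") = O, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List cpp_mhab_bwd(const arma::mat& gy, const arma::mat& xq, const arma::mat& xk,
                        const arma::mat& xv, const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, const arma::mat& O, const arma::cube& P,
                        int Lq, int Lk, int B, int heads,
                        const arma::mat& Wq, const arma::mat& Wk, const arma::mat& Wv,
                        const arma::mat& Wo) {
  const int d = xq.n_cols;
  const int dk = d / heads;
  const double s = std::sqrt((double)dk);
  mat gWo = O.t() * gy;
  rowvec gbo = sum(gy, 0);
  mat gO = gy * Wo.t();
  mat gQ(Q.n_rows, Q.n_cols, fill::zeros);
  mat gK(K.n_rows, K.n_cols, fill::zeros);
  mat gV(V.n_rows, V.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dk;
      const arma::mat& A = P.slice(b * heads + h);
      mat gOh = gO.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1);
      mat Vh = V.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
      mat gP = gOh * Vh.t();
      gV.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) = A.t() * gOh;
      mat gA = (gP - repmat(sum(gP % A, 1), 1, Lk)) % A;
      gQ.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) =
        gA * K.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) / s;
      gK.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) =
        gA.t() * Q.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) / s;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("gWq") = xq.t() * gQ, Rcpp::Named("gbq") = sum(gQ, 0),
    Rcpp::Named("gWk") = xk.t() * gK, Rcpp::Named("gbk") = sum(gK, 0),
    Rcpp::Named("gWv") = xv.t() * gV, Rcpp::Named("gbv") = sum(gV, 0),
    Rcpp::Named("gWo") = gWo, Rcpp::Named("gbo") = gbo,
    Rcpp::Named("gxq") = gQ * Wq.t(), Rcpp::Named("gxk") = gK * Wk.t(),
    Rcpp::Named("gxv") = gV * Wv.t());
}

// sigmoid approximation of GELU: x * sigma(1.702 x)
// [[Rcpp::export]]
arma::mat cpp_gelu(const arma::mat& x) {
  return x % (1.0 / (1.0 + exp(-1.702 * x)));
}

// [[Rcpp::export]]
arma::mat cpp_gelu_grad(const arma::mat& x) {
  mat s = 1.0 / (1.0 + exp(-1.702 * x));
  return s + 1.702 * (x % s % (1.0 - s));
}

// [[Rcpp::export]]
Rcpp::List cpp_layernorm_fwd(const arma::mat& x, const arma::vec& g, const arma::vec& b,
                             double eps) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec va = mean(xc % xc, 1);
  vec inv = 1.0 / sqrt(va + eps);
  mat xhat = xc.each_col() % inv;
  mat out = xhat.each_row() % g.t();
  out.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List cpp_layernorm_bwd(const arma::mat& gy, const arma::mat& xhat, const arma::vec& inv,
                             const arma::vec& g) {
  rowvec gg = sum(gy % xhat, 0);
  rowvec gb = sum(gy, 0);
  mat gxhat = gy.each_row() % g.t();
  vec m1 = mean(gxhat, 1);
  vec m2 = mean(gxhat % xhat, 1);
  mat gx = gxhat.each_col() - m1;
  gx -= xhat.each_col() % m2;
  gx.each_col() %= inv;
  return Rcpp::List::create(Rcpp::Named("gg") = gg, Rcpp::Named("gb") = gb,
                            Rcpp::Named("gx") = gx);
}
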