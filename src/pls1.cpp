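// PLS1 core: non-iterative NIPALS for a single response, with nested
// coefficient paths (one pass yields the model for every number of latent
// variables up to A) and a cross-validation driver that rescales inside
// each fold with train-only statistics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fit on already centered (and scaled) X, centered y. Returns the
// coefficient path B (p x Aeff): column a holds the coefficients of the
// a-component model in the given (scaled) space.
static mat pls1_path_core(mat X, vec y, int A, mat* W_out = nullptr,
                          mat* P_out = nullptr, vec* q_out = nullptr,
                          mat* T_out = nullptr) {
  const uword n = X.n_rows, p = X.n_cols;
  const int Amax = std::min<int>(A, std::min<uword>(n - 1, p));
  mat W(p, Amax, fill::zeros), P(p, Amax, fill::zeros);
  mat T(n, Amax, fill::zeros);
  vec q(Amax, fill::zeros);
  int Aeff = 0;
  for (int a = 0; a < Amax; ++a) {
    vec w = X.t() * y;
    double wn = norm(w);
    if (wn < 1e-300) break;
    w /= wn;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-300) break;
    vec pl = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    X -= t * pl.t();
    y -= qa * t;
    W.col(a) = w;
    P.col(a) = pl;
    T.col(a) = t;
    q(a) = qa;
    Aeff = a + 1;
  }
  if (Aeff == 0) {
    mat B(p, 1, fill::zeros);
    if (W_out) { *W_out = W.head_cols(0); }
    if (P_out) { *P_out = P.head_cols(0); }
    if (q_out) { *q_out = q.head(0); }
    if (T_out) { *T_out = T.head_cols(0); }
    return B;
  }
  W = W.head_cols(Aeff);
  P = P.head_cols(Aeff);
  T = T.head_cols(Aeff);
  q = q.head(Aeff);
  // R = W (P'W)^-1 ; P'W is unit upper triangular
  mat R = W * inv(trimatu(P.t() * W));
  mat B(p, Aeff, fill::zeros);
  vec acc(p, fill::zeros);
  for (int a = 0; a < Aeff; ++a) {
    acc += R.col(a) * q(a);
    B.col(a) = acc;
  }
  if (W_out) *W_out = W;
  if (P_out) *P_out = P;
  if (q_out) *q_out = q;
  if (T_out) *T_out = T;
  return B;
}

// [[Rcpp::export]]
Rcpp::List pls1_path(const arma::mat& X, const arma::vec& y, int A) {
  mat W, P, T;
  vec q;
  mat B = pls1_path_core(X, y, A, &W, &P, &q, &T);
  return Rcpp::List::create(Rcpp::Named("B") = B, Rcpp::Named("W") = W,
                            Rcpp::Named("P") = P, Rcpp::Named("q") = q,
                            Rcpp::Named("scores") = T);
}

// Cross-validation: rows of fold k are predicted by a model fit on the
// remaining rows, rescaled with the training rows' statistics. Returns an
// n x A prediction matrix (column a = a-component model, in original y
// units) and a p x K matrix of per-fold coefficients (scaled space) at the
// largest component count each fold supports.
// [[Rcpp::export]]
Rcpp::List pls1_cv(const arma::mat& X, const arma::vec& y,
                   const arma::ivec& fold, int A, bool scale) {
  const uword n = X.n_rows, p = X.n_cols;
  const ivec levels = unique(fold);
  const uword K = levels.n_elem;
  mat pred(n, (uword)A, fill::zeros);
  mat coefs(p, K, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    const uvec te = find(fold == levels(k));
    const uvec tr = find(fold != levels(k));
    if (tr.n_elem < 2) Rcpp::stop("fold leaves fewer than 2 training rows");
    mat Xtr = X.rows(tr);
    rowvec mu = mean(Xtr, 0);
    rowvec sdv = scale ? stddev(Xtr, 0, 0) : rowvec(p, fill::ones);
    sdv.elem(find(sdv == 0)).ones();  // degenerate column -> centered zeros
    Xtr.each_row() -= mu;
    Xtr.each_row() /= sdv;
    vec ytr = y.elem(tr);
    double ybar = mean(ytr);
    mat B = pls1_path_core(Xtr, ytr - ybar, A);
    mat Xte = X.rows(te);
    Xte.each_row() -= mu;
    Xte.each_row() /= sdv;
    mat pk = Xte * B;  // n_te x Aeff
    pk += ybar;
    const uword Aeff = pk.n_cols;
    for (uword a = 0; a < (uword)A; ++a)
      pred.submat(te, uvec{a}) = pk.col(std::min(a, Aeff - 1));
    coefs.col(k) = B.col(Aeff - 1);
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("coefs") = coefs);
}
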