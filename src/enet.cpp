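#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gaussian elastic net, glmnet parameterization:
//   (1/2n) * ||y - b0 - X b||^2 + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)
// Solved by covariance-update coordinate descent with warm starts along a
// decreasing lambda path. Efficient for p << n (here p ~ 13 predictors).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Core path solver on (already column-centred) data summaries.
//   Gn = X_c'X_c / n, q = X_c'y_c / n
// beta warm-started column to column; returns p x L coefficient matrix.
static inline double cd_sweep(const arma::mat& Gn, const arma::vec& q,
                              arma::vec& b, const arma::uvec& idx,
                              double l1, double l2) {
  double dmax = 0.0;
  const arma::uword p = q.n_elem;
  const double* qp = q.memptr();
  double* bp = b.memptr();
  for (arma::uword t = 0; t < idx.n_elem; ++t) {
    const arma::uword j = idx(t);
    const double bj = bp[j];
    // q_j - sum_{k != j} Gn_jk b_k  ==  q_j - (Gn b)_j + Gn_jj b_j
    const double* gj = Gn.colptr(j);
    double acc = 0.0;
    for (arma::uword k = 0; k < p; ++k) acc += gj[k] * bp[k];
    double num = qp[j] - acc + gj[j] * bj;
    double den = gj[j] + l2;
    double bnew = (den > 0.0) ? soft(num, l1) / den : 0.0;
    if (bnew != bj) {
      bp[j] = bnew;
      double d = std::abs(bnew - bj);
      if (d > dmax) dmax = d;
    }
  }
  return dmax;
}

static arma::mat path_solve(const arma::mat& Gn, const arma::vec& q,
                            double alpha, const arma::vec& lambda,
                            double tol, int maxit) {
  const arma::uword p = q.n_elem, L = lambda.n_elem;
  arma::mat betas(p, L, arma::fill::zeros);
  if (alpha == 0.0) {   // ridge: one eigendecomposition serves the path
    arma::vec d; arma::mat V;
    arma::eig_sym(d, V, Gn);
    arma::vec Vq = V.t() * q;
    for (arma::uword l = 0; l < L; ++l)
      betas.col(l) = V * (Vq / (d + lambda(l)));
    return betas;
  }
  arma::vec b(p, arma::fill::zeros);
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (arma::uword l = 0; l < L; ++l) {
    const double lam = lambda(l);
    const double l1 = lam * alpha, l2 = lam * (1.0 - alpha);
    int it = 0;
    while (it < maxit) {
      // full sweep (may activate new coordinates), then iterate the
      // active set to convergence; done when a full sweep moves nothing
      double dfull = cd_sweep(Gn, q, b, all, l1, l2);
      ++it;
      if (dfull < tol) break;
      arma::uvec active = arma::find(b != 0.0);
      while (it < maxit && cd_sweep(Gn, q, b, active, l1, l2) >= tol) ++it;
    }
    betas.col(l) = b;
  }
  return betas;
}

// [[Rcpp::export(name = ".enet_path_cpp")]]
List enet_path_cpp(const arma::mat& X, const arma::vec& y, double alpha,
                   const arma::vec& lambda, double tol = 1e-7,
                   int maxit = 100000) {
  const arma::uword n = X.n_rows;
  arma::rowvec xm = arma::mean(X, 0);
  double ym = arma::mean(y);
  arma::mat Xc = X.each_row() - xm;
  arma::vec yc = y - ym;
  arma::mat Gn = (Xc.t() * Xc) / double(n);
  arma::vec q = (Xc.t() * yc) / double(n);
  arma::mat betas = path_solve(Gn, q, alpha, lambda, tol, maxit);
  arma::rowvec a0 = ym - xm * betas;
  arma::irowvec nz(lambda.n_elem);
  for (arma::uword l = 0; l < lambda.n_elem; ++l)
    nz(l) = (int)arma::accu(betas.col(l) != 0.0);
  return List::create(_["beta"] = betas, _["a0"] = a0, _["nzero"] = nz);
}

// K-fold cross-validation at a fixed alpha over a shared lambda path.
// foldid: 1..K per observation. cvm = mean over all n held-out squared errors.
// nzero/beta are from the fit on the full data (the model actually exported).
// [[Rcpp::export(name = ".enet_cv_cpp")]]
List enet_cv_cpp(const arma::mat& X, const arma::vec& y,
                 const arma::ivec& foldid, double alpha,
                 const arma::vec& lambda, double tol = 1e-7,
                 int maxit = 100000) {
  const arma::uword n = X.n_rows, L = lambda.n_elem;
  const int K = foldid.max();
  arma::rowvec tot(L, arma::fill::zeros);
  for (int k = 1; k <= K; ++k) {
    arma::uvec te = arma::find(foldid == k);
    arma::uvec tr = arma::find(foldid != k);
    arma::mat Xtr = X.rows(tr), Xte = X.rows(te);
    arma::vec ytr = y.elem(tr), yte = y.elem(te);
    arma::rowvec xm = arma::mean(Xtr, 0);
    double ym = arma::mean(ytr);
    arma::mat Xc = Xtr.each_row() - xm;
    arma::vec yc = ytr - ym;
    arma::mat Gn = (Xc.t() * Xc) / double(Xtr.n_rows);
    arma::vec q = (Xc.t() * yc) / double(Xtr.n_rows);
    arma::mat betas = path_solve(Gn, q, alpha, lambda, tol, maxit);
    arma::rowvec a0 = ym - xm * betas;
    arma::mat pred = Xte * betas;          // n_te x L
    pred.each_row() += a0;
    pred.each_col() -= yte;
    tot += arma::sum(arma::square(pred), 0);
  }
  arma::rowvec cvm = tot / double(n);
  List full = enet_path_cpp(X, y, alpha, lambda, tol, maxit);
  return List::create(_["cvm"] = cvm, _["beta"] = full["beta"],
                      _["a0"] = full["a0"], _["nzero"] = full["nzero"]);
}

// CV over a whole alpha grid in one pass: the per-fold data summaries
// (centred Gram and correlation vector) are computed once and shared by all
// alphas, which dominates the cost of the bootstrap engine.
// lambda_mat: L x n_alpha, one decreasing path per alpha.
// [[Rcpp::export(name = ".enet_cv_grid_cpp")]]
List enet_cv_grid_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::ivec& foldid, const arma::vec& alphas,
                      const arma::mat& lambda_mat, double tol = 1e-7,
                      int maxit = 100000) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword L = lambda_mat.n_rows, nA = alphas.n_elem;
  const int K = foldid.max();

  std::vector<arma::mat> Gn_k(K), Xte_k(K);
  std::vector<arma::vec> q_k(K), yte_k(K);
  std::vector<arma::rowvec> xm_k(K);
  std::vector<double> ym_k(K);
  for (int k = 1; k <= K; ++k) {
    arma::uvec te = arma::find(foldid == k);
    arma::uvec tr = arma::find(foldid != k);
    arma::mat Xtr = X.rows(tr);
    arma::vec ytr = y.elem(tr);
    arma::rowvec xm = arma::mean(Xtr, 0);
    double ym = arma::mean(ytr);
    arma::mat Xc = Xtr.each_row() - xm;
    arma::vec yc = ytr - ym;
    Gn_k[k - 1] = (Xc.t() * Xc) / double(Xtr.n_rows);
    q_k[k - 1] = (Xc.t() * yc) / double(Xtr.n_rows);
    Xte_k[k - 1] = X.rows(te);
    yte_k[k - 1] = y.elem(te);
    xm_k[k - 1] = xm;
    ym_k[k - 1] = ym;
  }
  arma::rowvec xm_full = arma::mean(X, 0);
  double ym_full = arma::mean(y);
  arma::mat Xc_full = X.each_row() - xm_full;
  arma::vec yc_full = y - ym_full;
  arma::mat Gn_full = (Xc_full.t() * Xc_full) / double(n);
  arma::vec q_full = (Xc_full.t() * yc_full) / double(n);

  arma::mat cvm(L, nA);
  arma::imat nzero(L, nA);
  arma::mat beta_all(p, L * nA);
  for (arma::uword a = 0; a < nA; ++a) {
    const arma::vec lam = lambda_mat.col(a);
    arma::rowvec tot(L, arma::fill::zeros);
    for (int k = 0; k < K; ++k) {
      arma::mat betas = path_solve(Gn_k[k], q_k[k], alphas(a), lam, tol,
                                   maxit);
      arma::rowvec a0 = ym_k[k] - xm_k[k] * betas;
      arma::mat pred = Xte_k[k] * betas;
      pred.each_row() += a0;
      pred.each_col() -= yte_k[k];
      tot += arma::sum(arma::square(pred), 0);
    }
    cvm.col(a) = (tot / double(n)).t();
    arma::mat bfull = path_solve(Gn_full, q_full, alphas(a), lam, tol,
                                 maxit);
    beta_all.cols(a * L, a * L + L - 1) = bfull;
    for (arma::uword l = 0; l < L; ++l)
      nzero(l, a) = (int)arma::accu(bfull.col(l) != 0.0);
  }
  return List::create(_["cvm"] = cvm, _["nzero"] = nzero,
                      _["beta"] = beta_all);
}
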