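// Coordinate-descent solvers for the l1-penalized problems used throughout
// the package: node-wise lasso regressions (cross-lagged panel networks)
// and the graphical lasso (sparse Gaussian graphical models).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// Lasso by cyclic coordinate descent on the objective
//   (1/2n) ||y - X b||^2 + lambda ||b||_1 .
// Assumes nothing about standardization; the caller standardizes when
// standardized coefficients are wanted.
// [[Rcpp::export]]
List cpp_lasso_cd(const arma::mat& X, const arma::vec& y, double lambda,
                  double tol, int max_iter, arma::vec beta) {
  const int n = X.n_rows, p = X.n_cols;
  if ((int)beta.n_elem != p) beta.zeros(p);
  arma::vec xsq(p);
  for (int j = 0; j < p; ++j) xsq(j) = arma::dot(X.col(j), X.col(j)) / n;
  arma::vec r = y - X * beta;
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xsq(j) <= 0) { beta(j) = 0; continue; }
      double bj = beta(j);
      double rho = arma::dot(X.col(j), r) / n + xsq(j) * bj;
      double bnew = soft(rho, lambda) / xsq(j);
      if (bnew != bj) {
        r += X.col(j) * (bj - bnew);
        beta(j) = bnew;
        double d = std::fabs(bnew - bj);
        if (d > maxdiff) maxdiff = d;
      }
    }
    if (maxdiff < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["iter"] = it + 1,
                      _["converged"] = converged);
}

// Warm-started lasso along a decreasing penalty sequence.
// Returns a p x nlambda coefficient matrix.
// [[Rcpp::export]]
List cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                    const arma::vec& lambdas, double tol, int max_iter) {
  const int p = X.n_cols, nl = lambdas.n_elem;
  arma::mat betas(p, nl, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  bool all_ok = true;
  for (int k = 0; k < nl; ++k) {
    List fit = cpp_lasso_cd(X, y, lambdas(k), tol, max_iter, beta);
    beta = as<arma::vec>(fit["beta"]);
    if (!as<bool>(fit["converged"])) all_ok = false;
    betas.col(k) = beta;
  }
  return List::create(_["beta"] = betas, _["converged"] = all_ok);
}

// Inner lasso for one glasso column: minimize
//   (1/2) b' W11 b - s12' b + lambda ||b||_1
// with W11 positive definite. `c` carries W11 * b and is updated in place.
static void glasso_column(const arma::mat& W11, const arma::vec& s12,
                          double lambda, arma::vec& b, double tol,
                          int max_iter) {
  const int m = b.n_elem;
  arma::vec c = W11 * b;
  for (int it = 0; it < max_iter; ++it) {
    double maxdiff = 0.0;
    for (int k = 0; k < m; ++k) {
      double bk = b(k);
      double rho = s12(k) - c(k) + W11(k, k) * bk;
      double bnew = soft(rho, lambda) / W11(k, k);
      if (bnew != bk) {
        c += (bnew - bk) * W11.col(k);
        b(k) = bnew;
        double d = std::fabs(bnew - bk);
        if (d > maxdiff) maxdiff = d;
      }
    }
    if (maxdiff < tol) break;
  }
}

static arma::uvec others(int p, int j) {
  arma::uvec idx(p - 1);
  int k = 0;
  for (int i = 0; i < p; ++i) if (i != j) idx(k++) = i;
  return idx;
}

// Graphical lasso (block coordinate descent over covariance columns,
// Friedman-Hastie-Tibshirani style), penalizing off-diagonal entries only.
// Maximizes log det K - tr(SK) - lambda * sum_{i != j} |K_ij|.
// [[Rcpp::export]]
List cpp_glasso(const arma::mat& S, double lambda, double tol, int max_iter,
                Nullable<NumericMatrix> W0 = R_NilValue,
                Nullable<NumericMatrix> B0 = R_NilValue) {
  const int p = S.n_rows;
  arma::mat W = W0.isNotNull() ? as<arma::mat>(W0.get()) : arma::mat(S);
  W.diag() = S.diag();  // unpenalized diagonal: stationarity fixes W_ii = S_ii
  arma::mat B = B0.isNotNull() ? as<arma::mat>(B0.get())
                               : arma::mat(p, p, arma::fill::zeros);
  if (p == 1) {
    arma::mat K(1, 1);
    K(0, 0) = 1.0 / S(0, 0);
    return List::create(_["K"] = K, _["W"] = arma::mat(S), _["B"] = B,
                        _["iter"] = 0, _["converged"] = true);
  }
  const double inner_tol = tol / 10.0;
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::uvec idx = others(p, j);
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec b = B.col(j);
      b = b.elem(idx);
      glasso_column(W11, s12, lambda, b, inner_tol, max_iter);
      arma::vec w12 = W11 * b;
      for (int k = 0; k < p - 1; ++k) {
        double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > maxdiff) maxdiff = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = b(k);
      }
    }
    if (maxdiff < tol) { converged = true; break; }
  }
  // Recover the precision matrix from the final regression coefficients.
  arma::mat K(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx = others(p, j);
    arma::vec b = B.col(j);
    b = b.elem(idx);
    arma::vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double kjj = 1.0 / (W(j, j) - arma::dot(w12, b));
    K(j, j) = kjj;
    for (int k = 0; k < p - 1; ++k) {
      double val = -b(k) * kjj;
      K(idx(k), j) = val;
    }
  }
  // Symmetrize; keep exact zeros when both column solutions agree on zero.
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = (K(i, j) == 0.0 && K(j, i) == 0.0)
                     ? 0.0
                     : 0.5 * (K(i, j) + K(j, i));
      K(i, j) = v;
      K(j, i) = v;
    }
  return List::create(_["K"] = K, _["W"] = W, _["B"] = B, _["iter"] = it + 1,
                      _["converged"] = converged);
}

static double penalized_loglik(const arma::mat& K, const arma::mat& S,
                               double lambda) {
  double ld, sign;
  arma::log_det(ld, sign, K);
  if (sign <= 0) return -arma::datum::inf;
  double pen = arma::accu(arma::abs(K)) - arma::accu(arma::abs(K.diag()));
  return ld - arma::trace(S * K) - lambda * pen;
}

// [[Rcpp::export]]
double cpp_glasso_objective(const arma::mat& K, const arma::mat& S,
                            double lambda) {
  return penalized_loglik(K, S, lambda);
}

// Fit a whole warm-started glasso path and score each model by EBIC:
//   EBIC = -n (log det K - tr(SK)) + E log n + 4 E gamma log p ,
// E = nonzero upper-triangle off-diagonal entries of K.
// Returns the EBIC-minimizing precision matrix plus per-lambda diagnostics.
// [[Rcpp::export]]
List cpp_ggm_path(const arma::mat& S, double n, const arma::vec& lambdas,
                  double gamma, double tol, int max_iter) {
  const int p = S.n_rows, nl = lambdas.n_elem;
  arma::vec ebic(nl), loglik(nl);
  arma::ivec edges(nl);
  arma::mat W = S, B(p, p, arma::fill::zeros);
  arma::mat bestK;
  double best = arma::datum::inf;
  int best_idx = -1;
  bool all_ok = true;
  for (int k = 0; k < nl; ++k) {
    List fit = cpp_glasso(S, lambdas(k), tol, max_iter, wrap(W), wrap(B));
    if (!as<bool>(fit["converged"])) all_ok = false;
    W = as<arma::mat>(fit["W"]);
    B = as<arma::mat>(fit["B"]);
    arma::mat K = as<arma::mat>(fit["K"]);
    int E = 0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        if (K(i, j) != 0.0) ++E;
    double ld, sign;
    arma::log_det(ld, sign, K);
    double fitterm = ld - arma::trace(S * K);
    loglik(k) = fitterm;
    edges(k) = E;
    ebic(k) = -n * fitterm + E * std::log(n) + 4.0 * E * gamma * std::log((double)p);
    if (ebic(k) < best) {
      best = ebic(k);
      bestK = K;
      best_idx = k;
    }
  }
  return List::create(_["K"] = bestK, _["lambda_index"] = best_idx + 1,
                      _["ebic"] = ebic, _["edges"] = edges,
                      _["loglik"] = loglik, _["converged"] = all_ok);
}
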