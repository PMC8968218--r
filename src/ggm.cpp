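// Gaussian graphical model machinery: maximum-likelihood fit of a
// concentration matrix under a fixed zero pattern, a graphical-lasso
// path used only to seed candidate sparsity patterns, and the stepwise
// EBIC model search over single-edge changes.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fit the MLE concentration matrix K subject to K[i,j] = 0 for
// non-edges, by cycling node-wise regressions on neighbours until the
// implied covariance stabilises (the classical iterative algorithm for
// covariance selection).  On exit (K^-1)[i,j] = S[i,j] on edges and the
// diagonal, and K is exactly zero off-structure.
static bool fit_structure(const mat& S, const umat& adj, double tol, int maxit,
                          mat& K, mat& W, int& iters) {
  const int p = S.n_rows;
  W = S;
  K.zeros(p, p);
  std::vector<uvec> nb(p);
  for (int j = 0; j < p; ++j) {
    std::vector<unsigned int> v;
    for (int i = 0; i < p; ++i) if (i != j && adj(i, j)) v.push_back(i);
    nb[j] = uvec(v);
  }
  double scale = std::max(1e-12, abs(S).max());
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit && !converged; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      vec wj_new(p, fill::zeros);
      if (nb[j].n_elem > 0) {
        mat W11 = W.submat(nb[j], nb[j]);
        vec s12 = S.col(j); s12 = s12.elem(nb[j]);
        vec beta;
        if (!solve(beta, symmatu(W11), s12, solve_opts::likely_sympd))
          return false;
        // implied covariances between j and every other node
        for (int i = 0; i < p; ++i) {
          if (i == j) continue;
          double acc = 0.0;
          for (unsigned int k = 0; k < nb[j].n_elem; ++k)
            acc += W(i, nb[j](k)) * beta(k);
          wj_new(i) = acc;
        }
      }
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        delta = std::max(delta, std::fabs(wj_new(i) - W(i, j)));
        W(i, j) = wj_new(i);
        W(j, i) = wj_new(i);
      }
    }
    if (delta < tol * scale) converged = true;
  }
  iters = it;
  // recover K column-wise from the converged regressions
  for (int j = 0; j < p; ++j) {
    if (nb[j].n_elem == 0) {
      K(j, j) = 1.0 / S(j, j);
      continue;
    }
    mat W11 = W.submat(nb[j], nb[j]);
    vec s12 = S.col(j); s12 = s12.elem(nb[j]);
    vec beta;
    if (!solve(beta, symmatu(W11), s12, solve_opts::likely_sympd)) return false;
    double wjj = S(j, j);
    double kjj = 1.0 / (wjj - dot(s12, beta));
    if (!std::isfinite(kjj) || kjj <= 0) return false;
    K(j, j) = kjj;
    for (unsigned int k = 0; k < nb[j].n_elem; ++k)
      K(nb[j](k), j) = -beta(k) * kjj;
  }
  K = 0.5 * (K + K.t());
  // enforce exact structural zeros (symmetrisation keeps them at 0 anyway)
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j && !adj(i, j)) K(i, j) = 0.0;
  return converged;
}

static double gauss_loglik(const mat& S, const mat& K, double n) {
  double sign, ld;
  log_det(ld, sign, K);
  if (sign <= 0) return -datum::inf;
  return 0.5 * n * (ld - trace(S * K));
}

static double ebic_value(double loglik, int E, double n, int p, double gamma) {
  return -2.0 * loglik + E * std::log(n) + 4.0 * gamma * E * std::log((double)p);
}

// [[Rcpp::export]]
Rcpp::List cpp_ggm_fit(const arma::mat& S, const arma::umat& adj,
                       double tol = 1e-10, int maxit = 2000) {
  mat K, W;
  int iters = 0;
  bool ok = fit_structure(S, adj, tol, maxit, K, W, iters);
  double resid = 0.0;
  if (ok) {
    mat Sigma = inv_sympd(symmatu(K));
    for (unsigned int j = 0; j < S.n_cols; ++j)
      for (unsigned int i = 0; i < S.n_rows; ++i)
        if (i == j || adj(i, j))
          resid = std::max(resid, std::fabs(Sigma(i, j) - S(i, j)));
  }
  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("converged") = ok,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("resid") = resid);
}

// One graphical-lasso fit (block coordinate descent with an inner lasso
// solved by coordinate descent); returns the symmetrised (OR rule)
// adjacency of the nonzero regression coefficients.  B is updated in
// place so the path can warm-start.
static umat glasso_pattern(const mat& S, double lam, mat& W, mat& B,
                           double tol, int maxit) {
  const int p = S.n_rows;
  double scale = 0.0;
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j) scale = std::max(scale, std::fabs(S(i, j)));
  if (scale <= 0) scale = 1.0;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // inner lasso on column j
      for (int inner = 0; inner < 200; ++inner) {
        double d2 = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (int l = 0; l < p; ++l)
            if (l != j && l != k) r -= W(k, l) * B(l, j);
          double bnew = 0.0;
          if (r > lam) bnew = (r - lam) / W(k, k);
          else if (r < -lam) bnew = (r + lam) / W(k, k);
          d2 = std::max(d2, std::fabs(bnew - B(k, j)));
          B(k, j) = bnew;
        }
        if (d2 < 1e-7 * scale) break;
      }
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double acc = 0.0;
        for (int l = 0; l < p; ++l)
          if (l != j) acc += W(i, l) * B(l, j);
        delta = std::max(delta, std::fabs(acc - W(i, j)));
        W(i, j) = acc;
        W(j, i) = acc;
      }
    }
    if (delta < tol * scale) break;
  }
  umat adj(p, p, fill::zeros);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j && (B(i, j) != 0.0 || B(j, i) != 0.0)) adj(i, j) = 1;
  return adj;
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso_patterns(const arma::mat& S, const arma::vec& lambdas,
                               double tol = 1e-5, int maxit = 100) {
  const int p = S.n_rows;
  mat W = S, B(p, p, fill::zeros);
  Rcpp::List out(lambdas.n_elem);
  // lambdas run large -> small, so W and B warm-start along the path
  for (unsigned int l = 0; l < lambdas.n_elem; ++l) {
    W.diag() = S.diag() + lambdas(l);
    out[l] = glasso_pattern(S, lambdas(l), W, B, tol, maxit);
  }
  return out;
}

static std::string adj_key(const umat& adj) {
  std::string k;
  const int p = adj.n_rows;
  k.reserve(p * (p - 1) / 2);
  for (int j = 1; j < p; ++j)
    for (int i = 0; i < j; ++i) k.push_back(adj(i, j) ? '1' : '0');
  return k;
}

// Full ggmModSelect-style search: glasso path -> unregularized refits
// scored by EBIC -> best-first stepwise single-edge search.
// [[Rcpp::export]]
Rcpp::List cpp_ggm_select(const arma::mat& S, double n, double gamma,
                          const arma::vec& lambdas, double fit_tol = 1e-10,
                          int fit_maxit = 2000) {
  const int p = S.n_rows;
  Rcpp::List pats = cpp_glasso_patterns(S, lambdas);
  std::map<std::string, double> seen;  // pattern -> ebic
  umat best_adj(p, p, fill::zeros);
  mat best_K;
  double best_ebic = datum::inf;

  auto score_pattern = [&](const umat& adj, mat& K_out, double& ebic_out) -> bool {
    mat K, W; int iters;
    if (!fit_structure(S, adj, fit_tol, fit_maxit, K, W, iters)) return false;
    int E = accu(trimatu(adj, 1));
    double ll = gauss_loglik(S, K, n);
    if (!std::isfinite(ll)) return false;
    ebic_out = ebic_value(ll, E, n, p, gamma);
    K_out = K;
    return true;
  };

  // always include the empty and the saturated pattern as candidates
  std::vector<umat> candidates;
  candidates.push_back(umat(p, p, fill::zeros));
  umat full(p, p, fill::ones); full.diag().zeros();
  candidates.push_back(full);
  for (int l = 0; l < pats.size(); ++l) candidates.push_back(Rcpp::as<umat>(pats[l]));

  for (size_t c = 0; c < candidates.size(); ++c) {
    const umat& adj = candidates[c];
    std::string key = adj_key(adj);
    if (seen.count(key)) continue;
    mat K; double eb;
    if (!score_pattern(adj, K, eb)) { seen[key] = datum::inf; continue; }
    seen[key] = eb;
    if (eb < best_ebic) { best_ebic = eb; best_adj = adj; best_K = K; }
  }
  if (!std::isfinite(best_ebic))
    Rcpp::stop("no candidate structure could be fitted (is S positive definite?)");

  // best-first stepwise search over single-edge additions/removals
  std::vector<double> trace;
  trace.push_back(best_ebic);
  bool improved = true;
  while (improved) {
    improved = false;
    double step_best = best_ebic;
    umat step_adj; mat step_K;
    for (int j = 1; j < p; ++j) {
      for (int i = 0; i < j; ++i) {
        umat adj = best_adj;
        adj(i, j) = 1 - adj(i, j);
        adj(j, i) = adj(i, j);
        std::string key = adj_key(adj);
        double eb;
        mat K;
        auto it = seen.find(key);
        if (it != seen.end()) {
          eb = it->second;
          if (eb < step_best) {
            if (!score_pattern(adj, K, eb)) continue;  // refit to recover K
          }
        } else {
          if (!score_pattern(adj, K, eb)) { seen[key] = datum::inf; continue; }
          seen[key] = eb;
        }
        if (eb < step_best - 1e-9) {
          step_best = eb; step_adj = adj; step_K = K;
        }
      }
    }
    if (step_best < best_ebic - 1e-9) {
      best_ebic = step_best;
      best_adj = step_adj;
      if (step_K.n_rows == 0) score_pattern(step_adj, step_K, step_best);
      best_K = step_K;
      trace.push_back(best_ebic);
      improved = true;
    }
  }

  mat pcor(p, p, fill::zeros);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j && best_adj(i, j))
        pcor(i, j) = -best_K(i, j) / std::sqrt(best_K(i, i) * best_K(j, j));
  return Rcpp::List::create(Rcpp::Named("K") = best_K,
                            Rcpp::Named("adjacency") = best_adj,
                            Rcpp::Named("pcor") = pcor,
                            Rcpp::Named("ebic") = best_ebic,
                            Rcpp::Named("ebic_trace") = trace);
}
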