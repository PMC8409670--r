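// Core numerical routines: graph-constrained Gaussian covariance MLE by
// edge-wise iterative proportional fitting (IPF), penalized-likelihood graph
// search (greedy stepwise and exhaustive), and the graphical lasso by
// blockwise coordinate descent. Matrices are small (p <= a few dozen), so
// full p x p inversions inside sweeps are cheaper than bookkeeping low-rank
// updates and numerically safer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// status codes: 0 ok, 1 no_convergence, 2 not_positive_definite
struct IpfResult {
  mat omega;
  mat sigma;
  int status;
  int sweeps;
};

// Fit the precision matrix constrained to zeros off the adjacency; at the
// optimum sigma matches S on the diagonal and on every edge. omega must come
// in positive definite with exact zeros off-graph (diagonal start always
// qualifies); zeros are preserved because updates only touch edge blocks.
static IpfResult ipf_fit(const mat& S, const umat& adj, double tol,
                         int max_sweeps, const mat& omega_init) {
  const uword p = S.n_rows;
  IpfResult res;
  res.omega = omega_init;
  res.status = 1;
  res.sweeps = 0;

  if (!inv_sympd(res.sigma, res.omega)) {
    res.omega = diagmat(1.0 / S.diag());
    res.sigma = diagmat(S.diag());
  }

  std::vector<std::pair<uword, uword>> edges;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (adj(i, j) != 0) edges.push_back({i, j});

  uvec deg(p, fill::zeros);
  for (auto& e : edges) { deg(e.first)++; deg(e.second)++; }

  if (edges.empty()) {
    res.omega = diagmat(1.0 / S.diag());
    res.sigma = diagmat(S.diag());
    res.status = 0;
    return res;
  }

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    res.sweeps = sweep + 1;
    for (auto& e : edges) {
      const uword i = e.first, j = e.second;
      const double s11 = S(i, i), s22 = S(j, j), s12 = S(i, j);
      const double detS = s11 * s22 - s12 * s12;
      if (detS <= 0.0 || s11 <= 0.0) { res.status = 2; return res; }
      // 2x2 inverses of the target marginal and the current marginal
      const double g11 = res.sigma(i, i), g22 = res.sigma(j, j),
                   g12 = res.sigma(i, j);
      const double detG = g11 * g22 - g12 * g12;
      if (detG <= 0.0) { res.status = 2; return res; }
      const double a11 = s22 / detS - g22 / detG;
      const double a22 = s11 / detS - g11 / detG;
      const double a12 = -s12 / detS + g12 / detG;
      res.omega(i, i) += a11;
      res.omega(j, j) += a22;
      res.omega(i, j) += a12;
      res.omega(j, i) += a12;
      if (!inv_sympd(res.sigma, res.omega)) { res.status = 2; return res; }
    }
    // marginal fitting for isolated nodes (edge updates cover the rest)
    for (uword i = 0; i < p; ++i) {
      if (deg(i) == 0 && res.omega(i, i) != 1.0 / S(i, i)) {
        res.omega(i, i) = 1.0 / S(i, i);
        if (!inv_sympd(res.sigma, res.omega)) { res.status = 2; return res; }
      }
    }
    double err = 0.0;
    for (uword i = 0; i < p; ++i)
      err = std::max(err, std::fabs(res.sigma(i, i) - S(i, i)));
    for (auto& e : edges)
      err = std::max(err, std::fabs(res.sigma(e.first, e.second) -
                                    S(e.first, e.second)));
    if (err < tol) { res.status = 0; return res; }
  }
  return res;
}

// profile Gaussian log-likelihood at the constrained MLE:
// -(n/2) (p log 2pi + log det Sigma + p), using tr(Omega S) = p at the optimum
static double profile_loglik(const mat& sigma, double n_eff) {
  const uword p = sigma.n_rows;
  double ld, sign;
  log_det(ld, sign, sigma);
  return -0.5 * n_eff * (p * LOG2PI + ld + p);
}

// [[Rcpp::export]]
Rcpp::List cpp_ipf_ggm(const arma::mat& S, const arma::umat& adj, double tol,
                       int max_sweeps, Rcpp::Nullable<Rcpp::NumericMatrix> omega_init) {
  mat init;
  if (omega_init.isNotNull()) {
    init = Rcpp::as<mat>(omega_init.get());
  } else {
    init = diagmat(1.0 / S.diag());
  }
  IpfResult r = ipf_fit(S, adj, tol, max_sweeps, init);
  return Rcpp::List::create(Rcpp::Named("omega") = r.omega,
                            Rcpp::Named("sigma") = r.sigma,
                            Rcpp::Named("status") = r.status,
                            Rcpp::Named("sweeps") = r.sweeps);
}

// lexicographic key of an adjacency's edge set (row-major upper triangle)
static std::vector<uword> edge_key(const umat& adj) {
  std::vector<uword> key;
  const uword p = adj.n_rows;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (adj(i, j) != 0) key.push_back(i * p + j);
  return key;
}

// true if candidate (n_edges, key) beats incumbent under the tie rules:
// higher score; then fewer edges; then lexicographically smaller edge set
static bool better_graph(double cand_score, uword cand_ne,
                         const std::vector<uword>& cand_key, double inc_score,
                         uword inc_ne, const std::vector<uword>& inc_key,
                         double eps) {
  if (cand_score > inc_score + eps) return true;
  if (cand_score < inc_score - eps) return false;
  if (cand_ne != inc_ne) return cand_ne < inc_ne;
  return cand_key < inc_key;
}

// Greedy stepwise structure search: repeatedly toggle the single edge whose
// addition/removal most increases loglik - pen_per_edge * |E|; stop when no
// toggle improves. adj_init is the starting graph (empty for the standalone
// search, warm inside structural EM).
// [[Rcpp::export]]
Rcpp::List cpp_greedy_search(const arma::mat& S, double n_eff,
                             double pen_per_edge, const arma::umat& adj_init,
                             double tol, int max_sweeps) {
  const uword p = S.n_rows;
  const double eps = 1e-9;
  umat adj = adj_init;

  IpfResult cur = ipf_fit(S, adj, tol, max_sweeps, diagmat(1.0 / S.diag()));
  if (cur.status == 2)
    return Rcpp::List::create(Rcpp::Named("status") = 2);
  uword n_edges = accu(trimatu(adj, 1));
  double score = profile_loglik(cur.sigma, n_eff) - pen_per_edge * n_edges;

  const uword max_moves = p * (p - 1);  // generous cap
  for (uword move = 0; move < max_moves; ++move) {
    double best_score = score;
    uword best_ne = n_edges;
    std::vector<uword> best_key = edge_key(adj);
    int bi = -1, bj = -1;
    IpfResult best_fit;
    bool found = false;

    for (uword i = 0; i < p; ++i) {
      for (uword j = i + 1; j < p; ++j) {
        umat adj2 = adj;
        adj2(i, j) = 1 - adj2(i, j);
        adj2(j, i) = adj2(i, j);
        // warm start from the incumbent precision; zero the entry on removal
        mat init = cur.omega;
        if (adj2(i, j) == 0) { init(i, j) = 0.0; init(j, i) = 0.0; }
        IpfResult cand = ipf_fit(S, adj2, tol, max_sweeps, init);
        if (cand.status != 0) continue;
        uword ne2 = n_edges + (adj2(i, j) ? 1 : -1);
        double sc2 = profile_loglik(cand.sigma, n_eff) - pen_per_edge * ne2;
        std::vector<uword> key2 = edge_key(adj2);
        if (better_graph(sc2, ne2, key2, best_score, best_ne, best_key, eps)) {
          best_score = sc2; best_ne = ne2; best_key = key2;
          bi = (int)i; bj = (int)j; best_fit = cand; found = true;
        }
      }
    }
    if (!found) break;
    adj(bi, bj) = 1 - adj(bi, bj);
    adj(bj, bi) = adj(bi, bj);
    cur = best_fit;
    n_edges = best_ne;
    score = best_score;
  }

  return Rcpp::List::create(
      Rcpp::Named("adj") = adj, Rcpp::Named("omega") = cur.omega,
      Rcpp::Named("sigma") = cur.sigma, Rcpp::Named("score") = score,
      Rcpp::Named("loglik") = profile_loglik(cur.sigma, n_eff),
      Rcpp::Named("n_edges") = (int)n_edges, Rcpp::Named("status") = 0);
}

// Exhaustive search over all 2^(p(p-1)/2) graphs; p <= 5 enforced in R.
// [[Rcpp::export]]
Rcpp::List cpp_exhaustive_search(const arma::mat& S, double n_eff,
                                 double pen_per_edge, double tol,
                                 int max_sweeps) {
  const uword p = S.n_rows;
  std::vector<std::pair<uword, uword>> pairs;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) pairs.push_back({i, j});
  const uword m = pairs.size();
  const double eps = 1e-9;

  umat best_adj(p, p, fill::zeros);
  double best_score = -datum::inf;
  uword best_ne = 0;
  std::vector<uword> best_key;
  mat best_omega, best_sigma;
  bool any = false;

  for (uword mask = 0; mask < (uword(1) << m); ++mask) {
    umat adj(p, p, fill::zeros);
    uword ne = 0;
    for (uword b = 0; b < m; ++b) {
      if (mask & (uword(1) << b)) {
        adj(pairs[b].first, pairs[b].second) = 1;
        adj(pairs[b].second, pairs[b].first) = 1;
        ++ne;
      }
    }
    IpfResult fit = ipf_fit(S, adj, tol, max_sweeps, diagmat(1.0 / S.diag()));
    if (fit.status != 0) continue;
    double sc = profile_loglik(fit.sigma, n_eff) - pen_per_edge * ne;
    std::vector<uword> key = edge_key(adj);
    if (!any || better_graph(sc, ne, key, best_score, best_ne, best_key, eps)) {
      any = true;
      best_score = sc; best_ne = ne; best_key = key;
      best_adj = adj; best_omega = fit.omega; best_sigma = fit.sigma;
    }
  }
  if (!any) return Rcpp::List::create(Rcpp::Named("status") = 2);
  return Rcpp::List::create(
      Rcpp::Named("adj") = best_adj, Rcpp::Named("omega") = best_omega,
      Rcpp::Named("sigma") = best_sigma, Rcpp::Named("score") = best_score,
      Rcpp::Named("loglik") = profile_loglik(best_sigma, n_eff),
      Rcpp::Named("n_edges") = (int)best_ne, Rcpp::Named("status") = 0);
}

// Graphical lasso, off-diagonal L1 penalty only (diagonal of the covariance
// estimate stays at S): blockwise coordinate descent over columns with an
// inner lasso solved by coordinate descent. Exact zeros in the returned
// precision come from the soft-threshold operator.
// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double lambda, double tol,
                      int max_iter) {
  const uword p = S.n_rows;
  if (lambda <= 0.0) {
    mat omega;
    if (!inv_sympd(omega, S))
      return Rcpp::List::create(Rcpp::Named("status") = 2);
    omega = 0.5 * (omega + omega.t());
    return Rcpp::List::create(Rcpp::Named("omega") = omega,
                              Rcpp::Named("w") = S,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("status") = 0);
  }

  mat W = S;                     // working covariance estimate
  mat B(p, p, fill::zeros);      // lasso coefficients per column
  const double off_mean =
      accu(abs(S - diagmat(S.diag()))) / std::max(1.0, double(p * (p - 1)));
  const double thr = tol * std::max(off_mean, 1e-12);

  int it = 0;
  int status = 1;
  for (it = 1; it <= max_iter; ++it) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k)
        if (k != j) idx(c++) = k;
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      beta = beta.elem(idx);
      // inner coordinate descent
      for (int inner = 0; inner < 1000; ++inner) {
        double delta = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double x = s12(k) - (dot(V.col(k), beta) - V(k, k) * old);
          double b = 0.0;
          if (x > lambda) b = (x - lambda) / V(k, k);
          else if (x < -lambda) b = (x + lambda) / V(k, k);
          beta(k) = b;
          delta = std::max(delta, std::fabs(b - old));
        }
        if (delta < 1e-12) break;
      }
      vec w12 = V * beta;
      for (uword k = 0; k < p - 1; ++k) {
        max_change = std::max(max_change, std::fabs(W(idx(k), j) - w12(k)));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (max_change < thr) { status = 0; break; }
  }

  // recover the precision matrix column by column
  mat omega(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword k = 0; k < p; ++k)
      if (k != j) idx(c++) = k;
    vec beta = B.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double o22 = 1.0 / (W(j, j) - dot(w12, beta));
    omega(j, j) = o22;
    for (uword k = 0; k < p - 1; ++k)
      if (beta(k) != 0.0) omega(idx(k), j) = -beta(k) * o22;
  }
  // symmetrize, keeping exact zeros where either triangle was shrunk
  for (uword i = 0; i < p; ++i) {
    for (uword j = i + 1; j < p; ++j) {
      if (omega(i, j) == 0.0 || omega(j, i) == 0.0) {
        omega(i, j) = 0.0; omega(j, i) = 0.0;
      } else {
        double v = 0.5 * (omega(i, j) + omega(j, i));
        omega(i, j) = v; omega(j, i) = v;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("omega") = omega,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("status") = status);
}
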