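// Elicitation and MCMC kernels for the localized CAR model.
//
// Conventions: area indices are 0-based here (R wrappers convert); the
// global node is the last row/column (index n) of the extended precision.
// All randomness goes through R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// profiled approximate Gaussian log-likelihood of one state, constants
// dropped; tau2 is profiled as quad/m with a floor guarding z ~ 0
static double profile_loglik(double logdet, double quad, int m,
                             double tau2_floor) {
  double t2 = std::max(quad / m, tau2_floor);
  return 0.5 * logdet - 0.5 * m * std::log(t2) - quad / (2.0 * t2);
}

// dense extended precision Q(Wtilde) + eps I for a removal state
static arma::mat build_precision(const arma::imat& edges,
                                 const std::vector<char>& removed,
                                 int n, double eps) {
  int np = n + 1;
  arma::mat Q(np, np, arma::fill::zeros);
  arma::ivec wst(n, arma::fill::zeros);
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    int k = edges(e, 0), j = edges(e, 1);
    if (!removed[e]) {
      Q(k, j) -= 1.0; Q(j, k) -= 1.0;
      Q(k, k) += 1.0; Q(j, j) += 1.0;
    } else {
      wst[k] = 1; wst[j] = 1;
    }
  }
  for (int k = 0; k < n; ++k) {
    if (wst[k]) {
      Q(k, n) = -1.0; Q(n, k) = -1.0;
      Q(k, k) += 1.0; Q(n, n) += 1.0;
    }
  }
  Q.diag() += eps;
  return Q;
}

// Greedy elicitation of the edge-removal path. At each step the candidate
// log-determinants are obtained from the current state's Cholesky factor by
// the matrix-determinant lemma: removing edge (k,j) perturbs Q by
// -(e_k-e_j)(e_k-e_j)' plus, for each endpoint newly linked to the global
// node, +(e_k-e_*)(e_k-e_*)' -- a symmetric update of rank <= 3. Each
// accepted state's log-determinant is then recomputed exactly from a fresh
// factorization, so the cached values carry no accumulated error.
// [[Rcpp::export]]
List cpp_elicit_path(const arma::imat& edges, int n,
                     const arma::vec& zext, double eps,
                     double tau2_floor) {
  const int NE = edges.n_rows, np = n + 1;
  std::vector<char> removed(NE, 0);
  arma::ivec wst(n, arma::fill::zeros);
  const double zs = zext[n];

  IntegerVector removal_order(NE);
  NumericVector logdets(NE + 1), logliks(NE + 1);

  // quadratic form z'(Q+eps I)z of the current (all-retained) state
  double quad = eps * arma::dot(zext, zext);
  for (int e = 0; e < NE; ++e) {
    double d = zext[edges(e, 0)] - zext[edges(e, 1)];
    quad += d * d;
  }

  for (int step = 0; step < NE; ++step) {
    arma::mat Q = build_precision(edges, removed, n, eps);
    arma::mat L = arma::chol(Q, "lower");
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    logdets[step] = logdet;
    logliks[step] = profile_loglik(logdet, quad, np, tau2_floor);

    // columns of L^{-1}: Linv.col(k) = L^{-1} e_k
    arma::mat Linv = arma::inv(arma::trimatl(L));

    double best = -std::numeric_limits<double>::infinity();
    int best_e = -1;
    for (int e = 0; e < NE; ++e) {
      if (removed[e]) continue;
      int k = edges(e, 0), j = edges(e, 1);
      int a = wst[k] == 0, b = wst[j] == 0;
      int r = 1 + a + b;
      arma::mat V(np, r);
      V.col(0) = Linv.col(k) - Linv.col(j);
      arma::vec csign(r); csign[0] = -1.0;
      int c = 1;
      if (a) { V.col(c) = Linv.col(k) - Linv.col(n); csign[c] = 1.0; ++c; }
      if (b) { V.col(c) = Linv.col(j) - Linv.col(n); csign[c] = 1.0; ++c; }
      arma::mat M = arma::eye(r, r) + arma::diagmat(csign) * (V.t() * V);
      double ld_cand = logdet + std::log(arma::det(M));
      double dk = zext[k] - zext[j];
      double q_cand = quad - dk * dk;
      if (a) { double u = zext[k] - zs; q_cand += u * u; }
      if (b) { double u = zext[j] - zs; q_cand += u * u; }
      double ll = profile_loglik(ld_cand, q_cand, np, tau2_floor);
      if (ll > best) { best = ll; best_e = e; }  // ties: first canonical edge
    }

    int k = edges(best_e, 0), j = edges(best_e, 1);
    double dk = zext[k] - zext[j];
    quad -= dk * dk;
    if (!wst[k]) { double u = zext[k] - zs; quad += u * u; wst[k] = 1; }
    if (!wst[j]) { double u = zext[j] - zs; quad += u * u; wst[j] = 1; }
    removed[best_e] = 1;
    removal_order[step] = best_e + 1;  // back to 1-based
  }

  arma::mat Q = build_precision(edges, removed, n, eps);
  arma::mat L = arma::chol(Q, "lower");
  logdets[NE] = 2.0 * arma::sum(arma::log(L.diag()));
  logliks[NE] = profile_loglik(logdets[NE], quad, np, tau2_floor);

  return List::create(_["removalOrder"] = removal_order,
                      _["logdets"] = logdets,
                      _["loglik"] = logliks);
}

// exact log-determinant of one state's extended precision (testing utility)
// [[Rcpp::export]]
double cpp_state_logdet(const arma::imat& edges, const LogicalVector& rem,
                        int n, double eps) {
  std::vector<char> removed(rem.begin(), rem.end());
  arma::mat L = arma::chol(build_precision(edges, removed, n, eps), "lower");
  return 2.0 * arma::sum(arma::log(L.diag()));
}

// ---------------------------------------------------------------------------
// path machinery shared by the LCAR sampler

struct PathModel {
  arma::imat edges;        // 0-based endpoints
  arma::ivec rank;         // removal position of each edge, 1..NE
  arma::ivec min_rank;     // per area: earliest removal rank of an incident
                           // edge, NE+1 if none
  arma::vec logdets;       // NE+1 cached log-determinants
  double eps;
  int n, NE;

  PathModel(const arma::imat& e, const arma::ivec& rk,
            const arma::vec& ld, int n_, double eps_)
      : edges(e), rank(rk), logdets(ld), eps(eps_), n(n_),
        NE(e.n_rows) {
    min_rank.set_size(n);
    min_rank.fill(NE + 1);
    for (int k = 0; k < NE; ++k) {
      min_rank[edges(k, 0)] = std::min(min_rank[edges(k, 0)], (int)rank[k]);
      min_rank[edges(k, 1)] = std::min(min_rank[edges(k, 1)], (int)rank[k]);
    }
  }

  // edge e retained in state j iff its removal rank exceeds j
  bool retained(int e, int j) const { return rank[e] > j; }
  bool wstar(int k, int j) const { return min_rank[k] <= j; }

  // phi_tilde' (Q(Wtilde_j) + eps I) phi_tilde
  double quadform(int j, const arma::vec& phi, double phi_star) const {
    double q = eps * (arma::dot(phi, phi) + phi_star * phi_star);
    for (int e = 0; e < NE; ++e) {
      if (retained(e, j)) {
        double d = phi[edges(e, 0)] - phi[edges(e, 1)];
        q += d * d;
      }
    }
    for (int k = 0; k < n; ++k) {
      if (wstar(k, j)) {
        double d = phi[k] - phi_star;
        q += d * d;
      }
    }
    return q;
  }
};

// uniform draw from the proposal window {max(0, j-q), ..., min(NE, j+q)}
// excluding j itself; also reports the window size (Hastings correction)
static int draw_path_proposal(int j, int NE, int q, int* s_j_out) {
  int lo = std::max(0, j - q), hi = std::min(NE, j + q);
  int s_j = hi - lo;  // window size after excluding j
  *s_j_out = s_j;
  if (s_j <= 0) return j;
  int u = (int)std::floor(unif_rand() * s_j);
  if (u >= s_j) u = s_j - 1;
  int jp = lo + u;
  if (jp >= j) ++jp;  // skip the current index
  return jp;
}

// single path-index update, exported for exact-distribution tests; returns
// the new index (same routine the sampler loop uses)
static int update_path_index_impl(int j, const PathModel& pm,
                                  const arma::vec& phi, double phi_star,
                                  double tau2, int q, double quad_j,
                                  bool* acc) {
  *acc = false;
  int s_j;
  int jp = draw_path_proposal(j, pm.NE, q, &s_j);
  if (jp == j) return j;
  int s_jp;
  { // window size at the proposed index
    int lo = std::max(0, jp - q), hi = std::min(pm.NE, jp + q);
    s_jp = hi - lo;
  }
  double quad_jp = pm.quadform(jp, phi, phi_star);
  double logr = 0.5 * (pm.logdets[jp] - pm.logdets[j])
              - (quad_jp - quad_j) / (2.0 * tau2)
              + std::log((double)s_j) - std::log((double)s_jp);
  if (std::log(unif_rand()) < logr) { *acc = true; return jp; }
  return j;
}

// [[Rcpp::export]]
int cpp_update_path_index(int j, const arma::imat& edges,
                          const arma::ivec& rank, const arma::vec& logdets,
                          int n, double eps, const arma::vec& phi,
                          double phi_star, double tau2, int q) {
  PathModel pm(edges, rank, logdets, n, eps);
  bool acc;
  double quad_j = pm.quadform(j, phi, phi_star);
  return update_path_index_impl(j, pm, phi, phi_star, tau2, q, quad_j, &acc);
}

// conjugate inverse-gamma draw for a variance given its quadratic form;
// shape a + m/2, rate b + quad/2 (same routine the sampler loops use)
static double draw_variance(double quad, int m, double shape, double rate) {
  return 1.0 / R::rgamma(shape + 0.5 * m, 1.0 / (rate + 0.5 * quad));
}

// [[Rcpp::export]]
double cpp_draw_variance(double quad, int m, double shape, double rate) {
  return draw_variance(quad, m, shape, rate);
}

// ---------------------------------------------------------------------------
// LCAR Metropolis-within-Gibbs sampler (one chain)

// [[Rcpp::export]]
List cpp_lcar_mcmc(const arma::ivec& Y, const arma::vec& E,
                   const arma::mat& X, const arma::imat& edges,
                   const arma::ivec& rank, const arma::vec& logdets,
                   double eps, int q, int nburn, int nkeep,
                   double beta_prior_var, double tau2_shape,
                   double tau2_rate, double step_beta, double step_phi,
                   int j_init) {
  const int n = Y.n_elem, p = X.n_cols, NE = edges.n_rows;
  PathModel pm(edges, rank, logdets, n, eps);

  // adjacency lists: per area, incident (edge, neighbor)
  std::vector<std::vector<std::pair<int,int>>> adj(n);
  for (int e = 0; e < NE; ++e) {
    adj[edges(e, 0)].push_back({e, edges(e, 1)});
    adj[edges(e, 1)].push_back({e, edges(e, 0)});
  }

  arma::vec beta(p, arma::fill::zeros);
  double ybar = std::max(1e-8, (double)arma::sum(Y) / arma::sum(E));
  beta[0] = std::log(ybar);
  arma::vec phi(n, arma::fill::zeros);
  double phi_star = 0.0, tau2 = 0.1;
  int jpath = std::min(j_init, NE);

  arma::vec xb = X * beta;
  arma::vec sbeta(p); sbeta.fill(step_beta);
  arma::vec sphi(n); sphi.fill(step_phi);
  arma::ivec acc_b(p, arma::fill::zeros), acc_p(n, arma::fill::zeros);
  arma::ivec try_b(p, arma::fill::zeros), try_p(n, arma::fill::zeros);
  long acc_path = 0, try_path = 0, acc_b_tot = 0, acc_p_tot = 0;
  long try_b_tot = 0, try_p_tot = 0;

  arma::mat out_beta(nkeep, p), out_phi(nkeep, n);
  arma::vec out_ps(nkeep), out_t2(nkeep);
  arma::ivec out_j(nkeep);

  const int niter = nburn + nkeep;
  for (int it = 0; it < niter; ++it) {
    bool burn = it < nburn;

    // regression coefficients, single-site random walk
    for (int i = 0; i < p; ++i) {
      double d = sbeta[i] * norm_rand();
      double bn = beta[i] + d;
      double ll = 0.0;
      for (int k2 = 0; k2 < n; ++k2) {
        double xbn = xb[k2] + X(k2, i) * d;
        ll += Y[k2] * (xbn - xb[k2])
            - E[k2] * std::exp(phi[k2]) * (std::exp(xbn) - std::exp(xb[k2]));
      }
      ll -= (bn * bn - beta[i] * beta[i]) / (2.0 * beta_prior_var);
      ++try_b[i]; ++try_b_tot;
      if (std::log(unif_rand()) < ll) {
        xb += X.col(i) * d; beta[i] = bn;
        ++acc_b[i]; if (!burn) ++acc_b_tot;
      }
    }

    // area random effects, single-site random walk against the Poisson
    // likelihood and the LCAR full-conditional prior
    for (int k = 0; k < n; ++k) {
      int dk = 0; double nbsum = 0.0;
      for (auto& pr : adj[k]) {
        if (pm.retained(pr.first, jpath)) { ++dk; nbsum += phi[pr.second]; }
      }
      int ws = pm.wstar(k, jpath) ? 1 : 0;
      double prec = (dk + ws + eps) / tau2;
      double m = (nbsum + ws * phi_star) / (dk + ws + eps);
      double pn = phi[k] + sphi[k] * norm_rand();
      double mu = E[k] * std::exp(xb[k]);
      double ll = Y[k] * (pn - phi[k]) - mu * (std::exp(pn) - std::exp(phi[k]))
                - 0.5 * prec * ((pn - m) * (pn - m)
                                - (phi[k] - m) * (phi[k] - m));
      ++try_p[k]; ++try_p_tot;
      if (std::log(unif_rand()) < ll) {
        phi[k] = pn; ++acc_p[k]; if (!burn) ++acc_p_tot;
      }
    }

    // global random effect: exact Gaussian full conditional (Gibbs)
    {
      int S = 0; double ssum = 0.0;
      for (int k = 0; k < n; ++k)
        if (pm.wstar(k, jpath)) { ++S; ssum += phi[k]; }
      double prec = (S + eps) / tau2;
      phi_star = ssum / (S + eps) + norm_rand() / std::sqrt(prec);
    }

    // variance: conjugate inverse-gamma
    double quad_j = pm.quadform(jpath, phi, phi_star);
    tau2 = draw_variance(quad_j, n + 1, tau2_shape, tau2_rate);

    // path index
    if (NE > 0) {
      bool acc;
      int jn = update_path_index_impl(jpath, pm, phi, phi_star, tau2, q,
                                      quad_j, &acc);
      if (acc) jpath = jn;
      if (!burn) { ++try_path; if (acc) ++acc_path; }
    }

    // step-size adaptation during burn-in, frozen afterwards
    if (burn && (it + 1) % 100 == 0) {
      for (int i = 0; i < p; ++i) {
        double r = (double)acc_b[i] / std::max(1, (int)try_b[i]);
        if (r > 0.5) sbeta[i] *= 1.1; else if (r < 0.4) sbeta[i] /= 1.1;
        acc_b[i] = 0; try_b[i] = 0;
      }
      for (int k = 0; k < n; ++k) {
        double r = (double)acc_p[k] / std::max(1, (int)try_p[k]);
        if (r > 0.5) sphi[k] *= 1.1; else if (r < 0.4) sphi[k] /= 1.1;
        acc_p[k] = 0; try_p[k] = 0;
      }
    }

    if (!burn) {
      int s = it - nburn;
      out_beta.row(s) = beta.t();
      out_phi.row(s) = phi.t();
      out_ps[s] = phi_star; out_t2[s] = tau2; out_j[s] = jpath;
    }
  }

  double nb2 = std::max(1, nkeep * p);
  double np2 = std::max(1, nkeep * n);
  return List::create(
      _["beta"] = out_beta, _["phi"] = out_phi, _["phiStar"] = out_ps,
      _["tau2"] = out_t2, _["pathIndex"] = out_j,
      _["accBeta"] = (double)acc_b_tot / nb2,
      _["accPhi"] = (double)acc_p_tot / np2,
      _["accPath"] = try_path > 0 ? (double)acc_path / try_path : NA_REAL);
}

// ---------------------------------------------------------------------------
// BYM / IAR Metropolis-within-Gibbs sampler (one chain)
//
// Linear predictor x'beta + psi_k (+ theta_k): psi has an intrinsic CAR
// prior with on-the-fly sum-to-zero centering per connected component,
// theta is iid Gaussian; with include_theta = false this is the IAR model.

// [[Rcpp::export]]
List cpp_bym_mcmc(const arma::ivec& Y, const arma::vec& E,
                  const arma::mat& X, const arma::imat& edges,
                  const arma::ivec& comp, bool include_theta,
                  int nburn, int nkeep, double beta_prior_var,
                  double tau2_shape, double tau2_rate,
                  double step_beta, double step_phi) {
  const int n = Y.n_elem, p = X.n_cols, NE = edges.n_rows;
  std::vector<std::vector<int>> nbr(n);
  for (int e = 0; e < NE; ++e) {
    nbr[edges(e, 0)].push_back(edges(e, 1));
    nbr[edges(e, 1)].push_back(edges(e, 0));
  }
  int G = comp.max();  // number of connected components (1-based labels)
  arma::ivec csize(G, arma::fill::zeros);
  for (int k = 0; k < n; ++k) ++csize[comp[k] - 1];

  arma::vec beta(p, arma::fill::zeros);
  beta[0] = std::log(std::max(1e-8, (double)arma::sum(Y) / arma::sum(E)));
  arma::vec psi(n, arma::fill::zeros), theta(n, arma::fill::zeros);
  double tau2 = 0.1, sigma2 = 0.1;

  arma::vec xb = X * beta;
  arma::vec sbeta(p); sbeta.fill(step_beta);
  arma::vec spsi(n); spsi.fill(step_phi);
  arma::vec sth(n); sth.fill(step_phi);
  arma::ivec acc_b(p, arma::fill::zeros), try_b(p, arma::fill::zeros);
  arma::ivec acc_s(n, arma::fill::zeros), try_s(n, arma::fill::zeros);
  arma::ivec acc_t(n, arma::fill::zeros), try_t(n, arma::fill::zeros);
  long acc_b_tot = 0, acc_s_tot = 0, acc_t_tot = 0;

  arma::mat out_beta(nkeep, p), out_psi(nkeep, n), out_theta(nkeep, n);
  arma::vec out_t2(nkeep), out_s2(nkeep);

  const int niter = nburn + nkeep;
  for (int it = 0; it < niter; ++it) {
    bool burn = it < nburn;

    for (int i = 0; i < p; ++i) {
      double d = sbeta[i] * norm_rand();
      double bn = beta[i] + d;
      double ll = 0.0;
      for (int k = 0; k < n; ++k) {
        double re = psi[k] + theta[k];
        double xbn = xb[k] + X(k, i) * d;
        ll += Y[k] * (xbn - xb[k])
            - E[k] * std::exp(re) * (std::exp(xbn) - std::exp(xb[k]));
      }
      ll -= (bn * bn - beta[i] * beta[i]) / (2.0 * beta_prior_var);
      ++try_b[i];
      if (std::log(unif_rand()) < ll) {
        xb += X.col(i) * d; beta[i] = bn; ++acc_b[i];
        if (!burn) ++acc_b_tot;
      }
    }

    // structured effects
    for (int k = 0; k < n; ++k) {
      int dk = nbr[k].size();
      double nbsum = 0.0;
      for (int j : nbr[k]) nbsum += psi[j];
      double pn = psi[k] + spsi[k] * norm_rand();
      double mu = E[k] * std::exp(xb[k] + theta[k]);
      double ll = Y[k] * (pn - psi[k])
                - mu * (std::exp(pn) - std::exp(psi[k]));
      if (dk > 0) {
        double m = nbsum / dk, prec = dk / tau2;
        ll -= 0.5 * prec * ((pn - m) * (pn - m)
                            - (psi[k] - m) * (psi[k] - m));
      }
      ++try_s[k];
      if (std::log(unif_rand()) < ll) {
        psi[k] = pn; ++acc_s[k]; if (!burn) ++acc_s_tot;
      }
    }
    // per-component sum-to-zero centering (intercept absorbs the level)
    {
      arma::vec cmean(G, arma::fill::zeros);
      for (int k = 0; k < n; ++k) cmean[comp[k] - 1] += psi[k];
      for (int g = 0; g < G; ++g) cmean[g] /= csize[g];
      for (int k = 0; k < n; ++k) psi[k] -= cmean[comp[k] - 1];
    }

    double quad = 0.0;
    for (int e = 0; e < NE; ++e) {
      double d = psi[edges(e, 0)] - psi[edges(e, 1)];
      quad += d * d;
    }
    tau2 = draw_variance(quad, n - G, tau2_shape, tau2_rate);

    if (include_theta) {
      for (int k = 0; k < n; ++k) {
        double tn = theta[k] + sth[k] * norm_rand();
        double mu = E[k] * std::exp(xb[k] + psi[k]);
        double ll = Y[k] * (tn - theta[k])
                  - mu * (std::exp(tn) - std::exp(theta[k]))
                  - (tn * tn - theta[k] * theta[k]) / (2.0 * sigma2);
        ++try_t[k];
        if (std::log(unif_rand()) < ll) {
          theta[k] = tn; ++acc_t[k]; if (!burn) ++acc_t_tot;
        }
      }
      sigma2 = draw_variance(arma::dot(theta, theta), n,
                             tau2_shape, tau2_rate);
    }

    if (burn && (it + 1) % 100 == 0) {
      for (int i = 0; i < p; ++i) {
        double r = (double)acc_b[i] / std::max(1, (int)try_b[i]);
        if (r > 0.5) sbeta[i] *= 1.1; else if (r < 0.4) sbeta[i] /= 1.1;
        acc_b[i] = 0; try_b[i] = 0;
      }
      for (int k = 0; k < n; ++k) {
        double r = (double)acc_s[k] / std::max(1, (int)try_s[k]);
        if (r > 0.5) spsi[k] *= 1.1; else if (r < 0.4) spsi[k] /= 1.1;
        acc_s[k] = 0; try_s[k] = 0;
        r = (double)acc_t[k] / std::max(1, (int)try_t[k]);
        if (r > 0.5) sth[k] *= 1.1; else if (r < 0.4) sth[k] /= 1.1;
        acc_t[k] = 0; try_t[k] = 0;
      }
    }

    if (!burn) {
      int s = it - nburn;
      out_beta.row(s) = beta.t();
      out_psi.row(s) = psi.t();
      out_theta.row(s) = theta.t();
      out_t2[s] = tau2; out_s2[s] = sigma2;
    }
  }

  return List::create(
      _["beta"] = out_beta, _["phi"] = out_psi, _["theta"] = out_theta,
      _["tau2"] = out_t2, _["sigma2"] = out_s2,
      _["accBeta"] = (double)acc_b_tot / std::max(1, nkeep * p),
      _["accPhi"] = (double)acc_s_tot / std::max(1, nkeep * n),
      _["accTheta"] = include_theta
          ? (double)acc_t_tot / std::max(1, nkeep * n) : NA_REAL);
}
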