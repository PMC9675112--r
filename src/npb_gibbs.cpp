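// Gibbs sampler for the Gaussian linear model with zero-spiked
// Dirichlet-process priors on two selection blocks (exposure main effects
// and pairwise interactions), plus Normal priors on adjustment covariates.
//
// Base measure per block: pi0 * delta_0 + (1 - pi0) * N(0, tau^2).
// Cluster assignments follow the conjugate (marginalized) Polya urn with the
// point mass merged into a single spike cluster whose atom is exactly 0, so
// spike membership is an exact zero and PIPs are well defined.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct BlockState {
  std::vector<int> assign;      // cluster index per coefficient; 0 = spike
  std::vector<double> atom;     // atom per cluster; atom[0] == 0
  std::vector<int> csize;       // occupancy per cluster
  double alpha;                 // DP concentration
  double pi0;                   // base-measure mass at zero
};

int sample_categorical(const std::vector<double>& logw) {
  double mx = logw[0];
  for (double w : logw) mx = std::max(mx, w);
  double tot = 0.0;
  std::vector<double> w(logw.size());
  for (size_t i = 0; i < logw.size(); ++i) {
    w[i] = std::exp(logw[i] - mx);
    tot += w[i];
  }
  double u = R::runif(0.0, tot);
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return static_cast<int>(i);
  }
  return static_cast<int>(w.size()) - 1;
}

void remove_from_cluster(BlockState& st, int j) {
  int c = st.assign[j];
  st.csize[c]--;
  st.assign[j] = -1;
  if (c != 0 && st.csize[c] == 0) {
    int last = static_cast<int>(st.atom.size()) - 1;
    if (c != last) {
      st.atom[c] = st.atom[last];
      st.csize[c] = st.csize[last];
      for (size_t k = 0; k < st.assign.size(); ++k) {
        if (st.assign[k] == last) st.assign[k] = c;
      }
    }
    st.atom.pop_back();
    st.csize.pop_back();
  }
}

// One Polya-urn assignment sweep over a selection block (npb mode).
void update_block_npb(const arma::mat& C, const arma::vec& css, arma::vec& coef,
                      arma::vec& r, BlockState& st, double sigma2, double tau2) {
  int m = C.n_cols;
  for (int j = 0; j < m; ++j) {
    double bj = coef(j);
    if (bj != 0.0) r += C.col(j) * bj;  // residual without coefficient j
    remove_from_cluster(st, j);

    double s = arma::dot(C.col(j), r) / sigma2;
    double v = css(j) / sigma2;
    double V = v + 1.0 / tau2;

    int K = static_cast<int>(st.atom.size());
    std::vector<double> logw(K + 1);
    // spike cluster: occupancy + alpha * pi0 prior mass; likelihood ratio 1
    logw[0] = std::log(st.csize[0] + st.alpha * st.pi0);
    for (int c = 1; c < K; ++c) {
      double th = st.atom[c];
      logw[c] = std::log((double)st.csize[c]) + th * s - 0.5 * th * th * v;
    }
    // new slab cluster: alpha*(1-pi0) times the conjugate marginal ratio
    logw[K] = std::log(st.alpha * (1.0 - st.pi0) + 1e-300) +
              0.5 * std::log(1.0 / (tau2 * V)) + 0.5 * s * s / V;

    int pick = sample_categorical(logw);
    if (pick == K) {
      double mean = s / V;
      double th = R::rnorm(mean, std::sqrt(1.0 / V));
      st.atom.push_back(th);
      st.csize.push_back(1);
      st.assign[j] = K;
      coef(j) = th;
    } else {
      st.csize[pick]++;
      st.assign[j] = pick;
      coef(j) = st.atom[pick];
    }
    if (coef(j) != 0.0) r -= C.col(j) * coef(j);
  }
}

// Refresh slab-cluster atoms from their Normal full conditionals.
void update_atoms(const arma::mat& C, arma::vec& coef, arma::vec& r,
                  BlockState& st, double sigma2, double tau2) {
  int K = static_cast<int>(st.atom.size());
  int m = C.n_cols;
  for (int c = 1; c < K; ++c) {
    arma::vec u(C.n_rows, arma::fill::zeros);
    for (int j = 0; j < m; ++j) {
      if (st.assign[j] == c) u += C.col(j);
    }
    double old = st.atom[c];
    arma::vec rc = r + u * old;
    double V = arma::dot(u, u) / sigma2 + 1.0 / tau2;
    double mean = (arma::dot(u, rc) / sigma2) / V;
    double th = R::rnorm(mean, std::sqrt(1.0 / V));
    st.atom[c] = th;
    for (int j = 0; j < m; ++j) {
      if (st.assign[j] == c) coef(j) = th;
    }
    r = rc - u * th;
  }
}

// Independent spike-slab sweep (cluster-free limit; validation mode).
void update_block_indep(const arma::mat& C, const arma::vec& css,
                        arma::vec& coef, arma::vec& r, BlockState& st,
                        double sigma2, double tau2) {
  int m = C.n_cols;
  for (int j = 0; j < m; ++j) {
    double bj = coef(j);
    if (bj != 0.0) r += C.col(j) * bj;
    double s = arma::dot(C.col(j), r) / sigma2;
    double v = css(j) / sigma2;
    double V = v + 1.0 / tau2;
    double lw0 = std::log(st.pi0 + 1e-300);
    double lw1 = std::log(1.0 - st.pi0 + 1e-300) +
                 0.5 * std::log(1.0 / (tau2 * V)) + 0.5 * s * s / V;
    double mx = std::max(lw0, lw1);
    double p1 = std::exp(lw1 - mx) / (std::exp(lw0 - mx) + std::exp(lw1 - mx));
    if (R::unif_rand() < p1) {
      coef(j) = R::rnorm(s / V, std::sqrt(1.0 / V));
      st.assign[j] = 1;
      r -= C.col(j) * coef(j);
    } else {
      coef(j) = 0.0;
      st.assign[j] = 0;
    }
  }
}

// Escobar-West auxiliary-variable update of a DP concentration parameter.
double update_alpha(double alpha, int k, int m, double a, double b) {
  double eta = R::rbeta(alpha + 1.0, (double)m);
  double num = a + k - 1.0;
  double den = m * (b - std::log(eta));
  double pi_eta = num / (num + den);
  double shape = (R::unif_rand() < pi_eta) ? (a + k) : (a + k - 1.0);
  if (shape <= 0.0) shape = 1e-3;
  return R::rgamma(shape, 1.0 / (b - std::log(eta)));
}

int occupied_clusters(const BlockState& st) {
  int k = 0;
  for (int c : st.csize) {
    if (c > 0) ++k;
  }
  return k;
}

}  // namespace

// [[Rcpp::export(name = ".npb_gibbs")]]
List npb_gibbs(const arma::mat& X, const arma::mat& Z, const arma::mat& W,
               const arma::vec& y, List cfg) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int q = Z.n_cols;
  const int r_cols = W.n_cols;

  const int n_iter = as<int>(cfg["n_iter"]);
  const int n_burn = as<int>(cfg["n_burn"]);
  const int thin = as<int>(cfg["thin"]);
  const double a1 = as<double>(cfg["a1"]), b1 = as<double>(cfg["b1"]);
  const double a2 = as<double>(cfg["a2"]), b2 = as<double>(cfg["b2"]);
  const double tau2 = std::pow(as<double>(cfg["slab_sd"]), 2);
  const double api = as<double>(cfg["a_pi"]), bpi = as<double>(cfg["b_pi"]);
  const double c2 = std::pow(as<double>(cfg["covariate_prior_sd"]), 2);
  const double asig = as<double>(cfg["a_sigma"]), bsig = as<double>(cfg["b_sigma"]);
  const bool indep = as<std::string>(cfg["mode"]) == "independent_spike_slab";
  const double fixed_sigma2 = as<double>(cfg["fixed_sigma2"]);  // <= 0: sample
  const double fixed_pi0 = as<double>(cfg["fixed_pi0"]);        // < 0: sample

  const int nkeep = (n_iter - n_burn) / thin;
  if (nkeep < 1) stop("n_iter too small: no draws retained");

  arma::vec css_x(p), css_z(std::max(q, 1));
  for (int j = 0; j < p; ++j) {
    css_x(j) = arma::dot(X.col(j), X.col(j));
    if (!std::isfinite(css_x(j)) || css_x(j) <= 0)
      stop("degenerate main-effect column %d", j + 1);
  }
  for (int j = 0; j < q; ++j) {
    css_z(j) = arma::dot(Z.col(j), Z.col(j));
    if (!std::isfinite(css_z(j)) || css_z(j) <= 0)
      stop("degenerate interaction column %d", j + 1);
  }

  BlockState st1, st2;
  st1.assign.assign(p, 0); st1.atom.assign(1, 0.0); st1.csize.assign(1, p);
  st2.assign.assign(q, 0); st2.atom.assign(1, 0.0); st2.csize.assign(1, q);
  st1.alpha = 1.0; st2.alpha = 1.0;
  st1.pi0 = (fixed_pi0 >= 0) ? fixed_pi0 : 0.5;
  st2.pi0 = st1.pi0;

  arma::vec beta(p, arma::fill::zeros), zeta(std::max(q, 1), arma::fill::zeros);
  arma::vec gamma_c(std::max(r_cols, 1), arma::fill::zeros);
  double sigma2 = (fixed_sigma2 > 0) ? fixed_sigma2 : arma::var(y);
  if (sigma2 <= 0) sigma2 = 1.0;

  arma::vec r = y;  // residual given all-zero start
  arma::mat WtW;
  if (r_cols > 0) WtW = W.t() * W;

  arma::mat beta_draws(nkeep, p), zeta_draws(nkeep, std::max(q, 1));
  arma::mat gamma_draws(nkeep, std::max(r_cols, 1));
  arma::vec sig_draws(nkeep), a1_draws(nkeep), a2_draws(nkeep);
  arma::vec pi1_draws(nkeep), pi2_draws(nkeep);
  arma::ivec k1_draws(nkeep), k2_draws(nkeep);

  int keep = 0;
  for (int t = 1; t <= n_iter; ++t) {
    if (t % 500 == 0) Rcpp::checkUserInterrupt();

    if (indep) {
      update_block_indep(X, css_x, beta, r, st1, sigma2, tau2);
      if (q > 0) update_block_indep(Z, css_z, zeta, r, st2, sigma2, tau2);
    } else {
      update_block_npb(X, css_x, beta, r, st1, sigma2, tau2);
      update_atoms(X, beta, r, st1, sigma2, tau2);
      if (q > 0) {
        update_block_npb(Z, css_z, zeta, r, st2, sigma2, tau2);
        update_atoms(Z, zeta, r, st2, sigma2, tau2);
      }
    }

    if (r_cols > 0) {
      arma::vec rw = r + W * gamma_c.head(r_cols);
      arma::mat A = WtW / sigma2;
      A.diag() += 1.0 / c2;
      arma::mat Achol = arma::chol(A);  // upper
      arma::vec mean = arma::solve(A, W.t() * rw / sigma2,
                                   arma::solve_opts::likely_sympd);
      arma::vec zdraw(r_cols);
      for (int i = 0; i < r_cols; ++i) zdraw(i) = R::norm_rand();
      gamma_c.head(r_cols) = mean + arma::solve(arma::trimatu(Achol), zdraw);
      r = rw - W * gamma_c.head(r_cols);
    }

    if (fixed_sigma2 <= 0) {
      double ssr = arma::dot(r, r);
      sigma2 = 1.0 / R::rgamma(asig + 0.5 * n, 1.0 / (bsig + 0.5 * ssr));
    }

    if (!indep) {
      st1.alpha = update_alpha(st1.alpha, occupied_clusters(st1), p, a1, b1);
      if (q > 0)
        st2.alpha = update_alpha(st2.alpha, occupied_clusters(st2), q, a2, b2);
    }

    if (fixed_pi0 < 0) {
      int n0 = 0;
      for (int j = 0; j < p; ++j) n0 += (beta(j) == 0.0);
      st1.pi0 = R::rbeta(api + n0, bpi + (p - n0));
      if (q > 0) {
        int m0 = 0;
        for (int j = 0; j < q; ++j) m0 += (zeta(j) == 0.0);
        st2.pi0 = R::rbeta(api + m0, bpi + (q - m0));
      }
    }

    if (t > n_burn && (t - n_burn) % thin == 0) {
      beta_draws.row(keep) = beta.t();
      if (q > 0) zeta_draws.row(keep) = zeta.head(q).t();
      if (r_cols > 0) gamma_draws.row(keep) = gamma_c.head(r_cols).t();
      sig_draws(keep) = sigma2;
      a1_draws(keep) = st1.alpha;
      a2_draws(keep) = st2.alpha;
      pi1_draws(keep) = st1.pi0;
      pi2_draws(keep) = st2.pi0;
      k1_draws(keep) = occupied_clusters(st1);
      k2_draws(keep) = occupied_clusters(st2);
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_draws,
    _["zeta"] = (q > 0) ? zeta_draws : arma::mat(nkeep, 0),
    _["gamma"] = (r_cols > 0) ? gamma_draws : arma::mat(nkeep, 0),
    _["sigma2"] = sig_draws,
    _["alpha1"] = a1_draws, _["alpha2"] = a2_draws,
    _["pi0_main"] = pi1_draws, _["pi0_interaction"] = pi2_draws,
    _["k_main"] = k1_draws, _["k_interaction"] = k2_draws);
}
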