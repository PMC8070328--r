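// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

double rpg1(double z);

// inverse-Gaussian(mu, lambda), Michael-Schucany-Haas transformation method
static double rinvgauss(double mu, double lambda) {
  double y = norm_rand();
  y *= y;
  double x = mu + 0.5 * mu * mu * y / lambda
    - 0.5 * (mu / lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-300;  // numerical underflow guard
  if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
  return x;
}

// Log conditional density (up to a constant) of a variance-component scale
// gamma for one smoother block.
//   ridge: p(sigma | u)  propto sigma^-K  exp(-S/(2 sigma^2)) p(sigma), S = sum u^2
//   lasso: p(tau | a)    propto tau^-2K   exp(-S/(2 tau^2))   p(tau),   S = sum a
// (the Laplace scale enters only through the exponential mixing rate 1/(2 tau^2))
// prior: 0 = Uniform(0, 100), 1 = half-Cauchy(hc_scale)
static double gamma_logtarget(double g, double S, int Kb, int penalty,
                              int prior, double hc_scale) {
  if (g <= 0.0) return -INFINITY;
  double lp;
  if (prior == 0) {
    if (g >= 100.0) return -INFINITY;
    lp = 0.0;
  } else {
    lp = -std::log(g * g + hc_scale * hc_scale);
  }
  double npow = (penalty == 1) ? 2.0 * Kb : (double)Kb;
  return -npow * std::log(g) - S / (2.0 * g * g) + lp;
}

// Exact conditional update of gamma under the Uniform(0, 100) prior via the
// precision scale: with v = gamma^-2 the conditional is
//   lasso: v ~ Gamma(K - 1/2,   rate S/2) truncated to v > 1e-4
//   ridge: v ~ Gamma((K - 1)/2, rate S/2) truncated to v > 1e-4
// (the truncation enforces gamma < 100). Returns a negative value when the
// shape parameter is degenerate (K too small) so the caller falls back to
// slice sampling.
static double gamma_gibbs_uniform(double S, int Kb, int penalty) {
  double shape = (penalty == 1) ? Kb - 0.5 : 0.5 * (Kb - 1.0);
  if (shape < 0.25 || S <= 1e-300) return -1.0;
  for (int tries = 0; tries < 100; ++tries) {
    double v = R::rgamma(shape, 2.0 / S);
    if (v > 1e-4) return 1.0 / std::sqrt(v);
  }
  return -1.0;
}

// univariate slice sampler (Neal 2003): shrinkage over the full support for
// the bounded Uniform prior, stepping-out for the half-Cauchy
static double slice_gamma(double g0, double S, int Kb, int penalty,
                          int prior, double hc_scale) {
  double ly = gamma_logtarget(g0, S, Kb, penalty, prior, hc_scale) - exp_rand();
  double L, Rr;
  if (prior == 0) {
    L = 0.0;
    Rr = 100.0;
  } else {
    double w = 1.0 + g0;
    L = g0 - w * unif_rand();
    if (L < 0.0) L = 0.0;
    Rr = L + w;
    int m = 100;
    int j = (int)std::floor(unif_rand() * m);
    int k = m - 1 - j;
    while (j-- > 0 && L > 0.0 &&
           gamma_logtarget(L, S, Kb, penalty, prior, hc_scale) > ly) {
      L -= w;
      if (L < 0.0) { L = 0.0; break; }
    }
    while (k-- > 0 &&
           gamma_logtarget(Rr, S, Kb, penalty, prior, hc_scale) > ly) {
      Rr += w;
    }
  }
  for (int it = 0; it < 1000; ++it) {
    double g1 = L + unif_rand() * (Rr - L);
    if (gamma_logtarget(g1, S, Kb, penalty, prior, hc_scale) >= ly) return g1;
    if (g1 < g0) L = g1; else Rr = g1;
  }
  return g0;
}

// Blocked Gibbs sampler for the logistic semiparametric mixed model.
//   y: 0/1 outcomes;  X: n x p fixed effects;  Z: n x K penalized basis
//   blocks: 1-based smoother-block index per Z column (length K)
//   penalty: 0 = ridge (normal prior on u), 1 = lasso (Laplace prior on u)
//   gamma_prior: 0 = Uniform(0,100), 1 = half-Cauchy(hc_scale)
//   gamma_fixed: length 0 (gamma sampled) or n_blocks (held fixed)
//   prior_only: skip the likelihood entirely; chain targets the joint prior
// Updates per sweep: Polya-Gamma auxiliaries -> (beta, u) joint Gaussian draw
// -> Laplace scale-mixture auxiliaries (lasso) -> slice update of each gamma.
// All randomness via R's RNG, so set.seed() in R makes runs reproducible.
// [[Rcpp::export(rng = true)]]
Rcpp::List gibbs_spmm(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                      const arma::ivec& blocks, int penalty, int gamma_prior,
                      double hc_scale, double beta_prior_var,
                      const arma::vec& gamma_fixed, bool prior_only,
                      int n_iter, int burn_in, int thin,
                      const arma::vec& beta_init, double gamma_init) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int K = Z.n_cols;
  const int d = p + K;
  const int B = (K > 0) ? blocks.max() : 0;
  const bool fix_gamma = gamma_fixed.n_elem > 0;

  arma::mat W = arma::join_rows(X, Z);
  arma::vec kappa = y - 0.5;

  arma::vec theta(d, arma::fill::zeros);
  theta.head(p) = beta_init;
  arma::vec gam(B > 0 ? B : 1);
  gam.fill(gamma_init);
  if (fix_gamma) gam = gamma_fixed;
  arma::vec a(K, arma::fill::ones);  // Laplace scale-mixture variances

  // per-block column index lists and sizes
  std::vector<std::vector<int>> bidx(B);
  for (int k = 0; k < K; ++k) bidx[blocks[k] - 1].push_back(k);

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat theta_draws(n_keep, d);
  arma::mat gamma_draws(n_keep, B > 0 ? B : 1);
  arma::mat a_draws(penalty == 1 ? n_keep : 0, penalty == 1 ? K : 0);

  int kept = 0;
  arma::ivec boundary_count(B > 0 ? B : 1, arma::fill::zeros);

  arma::vec omega(n), eta(n), b(d), m(d), zdraw(d);
  arma::mat Q(d, d), R;

  for (int it = 1; it <= n_iter; ++it) {
    // --- (beta, u) update ---
    if (!prior_only) {
      eta = W * theta;
      for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);
      // posterior precision = W' diag(omega) W + prior precision
      Q = W.t() * (W.each_col() % omega);
      for (int j = 0; j < p; ++j) Q(j, j) += 1.0 / beta_prior_var;
      for (int k = 0; k < K; ++k) {
        double prec = (penalty == 1) ? 1.0 / a[k]
                                     : 1.0 / (gam[blocks[k] - 1] * gam[blocks[k] - 1]);
        Q(p + k, p + k) += prec;
      }
      b = W.t() * kappa;
      if (!arma::chol(R, Q)) {
        Rcpp::stop("posterior precision not positive definite at iteration %d", it);
      }
      // mean solve and N(m, Q^-1) draw through the Cholesky factor
      m = arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), b));
      for (int j = 0; j < d; ++j) zdraw[j] = norm_rand();
      theta = m + arma::solve(arma::trimatu(R), zdraw);
    } else {
      for (int j = 0; j < p; ++j) theta[j] = norm_rand() * std::sqrt(beta_prior_var);
      for (int k = 0; k < K; ++k) {
        double sd = (penalty == 1) ? std::sqrt(a[k]) : gam[blocks[k] - 1];
        theta[p + k] = norm_rand() * sd;
      }
    }

    if (!theta.is_finite()) {
      Rcpp::stop("divergent chain: non-finite state at iteration %d", it);
    }

    // --- Laplace scale-mixture auxiliaries ---
    if (penalty == 1) {
      for (int k = 0; k < K; ++k) {
        double tau = gam[blocks[k] - 1];
        double uk = std::fabs(theta[p + k]);
        if (uk < 1e-12) {
          // degenerate GIG limit: a_k | u_k=0 ~ Gamma(1/2, rate 1/(2 tau^2))
          a[k] = R::rgamma(0.5, 2.0 * tau * tau);
        } else {
          double x = rinvgauss(1.0 / (tau * uk), 1.0 / (tau * tau));
          a[k] = 1.0 / x;
        }
        if (a[k] < 1e-12) a[k] = 1e-12;
      }
    }

    // --- variance-component scales ---
    if (!fix_gamma) {
      for (int bb = 0; bb < B; ++bb) {
        double S = 0.0;
        for (int k : bidx[bb]) {
          S += (penalty == 1) ? a[k] : theta[p + k] * theta[p + k];
        }
        int Kb = (int)bidx[bb].size();
        double gnew = -1.0;
        if (gamma_prior == 0) gnew = gamma_gibbs_uniform(S, Kb, penalty);
        if (gnew < 0.0) {
          gnew = slice_gamma(gam[bb], S, Kb, penalty, gamma_prior, hc_scale);
        }
        gam[bb] = gnew;
        if (gamma_prior == 0 && gam[bb] > 99.0) boundary_count[bb]++;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      theta_draws.row(kept) = theta.t();
      gamma_draws.row(kept) = gam.t();
      if (penalty == 1) a_draws.row(kept) = a.t();
      ++kept;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = theta_draws,
    Rcpp::Named("gamma") = gamma_draws,
    Rcpp::Named("a") = a_draws,
    Rcpp::Named("boundary_count") = boundary_count,
    Rcpp::Named("n_iter") = n_iter);
}
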