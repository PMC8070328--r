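# Shared fixtures and independent oracles, built in code at test time.

# small binary dataset with an LRTP design attached
toy_data <- function(n = 40, K = 3, seed = 1, fname = "concave") {
  fn <- calibrate_function(fname)
  d <- generate_dataset(fn, n, seed = seed)
  d$design <- lrtp_design(d$x, place_knots(d$x, K))
  d
}

# Laplace(0, tau) draws for Monte-Carlo prior checks
rlaplace <- function(n, tau) {
  sample(c(-1, 1), n, replace = TRUE) * stats::rexp(n, rate = 1 / tau)
}

# Dense-grid integration of exp(log_posterior) for a tiny ridge instance
# with fixed gamma: the sampler-correctness oracle. Returns posterior means
# of (beta0, beta1, u1, ..., uK) by brute-force quadrature over a grid
# centered at the posterior mode, +/- span posterior-curvature sd's.
grid_posterior_means <- function(d, spec, sigma, ng = 23, span = 5) {
  W <- cbind(d$design$X, d$design$Z)
  p <- ncol(d$design$X)
  K <- ncol(d$design$Z)
  sdb <- sqrt(spec$beta_prior_var)
  logpost <- function(th) {
    eta <- drop(W %*% th)
    -sum((1 - d$y) * eta + log1p(exp(-eta))) +
      sum(stats::dnorm(th[1:p], 0, sdb, log = TRUE)) +
      sum(stats::dnorm(th[(p + 1):(p + K)], 0, sigma, log = TRUE))
  }
  opt <- stats::optim(rep(0, p + K), function(th) -logpost(th),
                      method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  grids <- lapply(seq_len(p + K), function(j) {
    seq(opt$par[j] - span * se[j], opt$par[j] + span * se[j], length.out = ng)
  })
  gr <- as.matrix(expand.grid(grids))
  eta <- gr %*% t(W)
  ll <- -rowSums((1 - rep(d$y, each = nrow(gr))) * eta + log1p(exp(-eta)))
  lp <- ll + rowSums(stats::dnorm(gr[, 1:p, drop = FALSE], 0, sdb, log = TRUE)) +
    rowSums(stats::dnorm(gr[, (p + 1):(p + K), drop = FALSE], 0, sigma, log = TRUE))
  wts <- exp(lp - max(lp))
  wts <- wts / sum(wts)
  colSums(gr * wts)
}

# posterior means and batch-means MC standard errors of the coefficient
# vector of a fit, in design order
fit_theta_moments <- function(fit) {
  nm <- colnames(fit$draws[[1]]$theta)
  list(mean = vapply(nm, function(p) mean(posterior_draws(fit, p)), numeric(1)),
       mcse = vapply(nm, function(p) mcse_batch(posterior_draws(fit, p)), numeric(1)))
}
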