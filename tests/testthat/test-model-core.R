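test_that("log likelihood matches the Bernoulli-logit oracle", {
  d <- toy_data(n = 25, K = 3, seed = 4)
  K <- ncol(d$design$Z)

  # theta = 0: every probability is 1/2
  th0 <- param_state(beta = c(0, 0), u = rep(0, K))
  expect_equal(log_likelihood(th0, d), -25 * log(2))

  # saturated single observation
  d1 <- spmm_data(y = 1, x = 0.5,
                  design = structure(list(X = matrix(c(1, 0.5), 1),
                                          Z = matrix(0.2, 1, 1),
                                          blocks = 1L), class = "spmm_design"))
  th_big <- param_state(beta = c(50, 0), u = 0)
  expect_lt(abs(log_likelihood(th_big, d1)), 1e-15)

  # hand-set state vs independent per-observation Bernoulli log-pmf sum
  set.seed(8)
  th <- param_state(beta = c(-0.3, 1.2), u = rnorm(K))
  eta <- drop(d$design$X %*% th$beta + d$design$Z %*% th$u)
  oracle <- sum(stats::dbinom(d$y, 1, stats::plogis(eta), log = TRUE))
  expect_equal(log_likelihood(th, d), oracle)
  expect_equal(success_prob(th, d), stats::plogis(eta))

  # permutation invariance of the observations
  i <- sample(length(d$y))
  dperm <- d
  dperm$y <- d$y[i]
  dperm$design$X <- d$design$X[i, ]
  dperm$design$Z <- d$design$Z[i, , drop = FALSE]
  expect_equal(log_likelihood(th, dperm), log_likelihood(th, d))

  # extreme linear predictors stay finite (overflow-safe arithmetic)
  th_ex <- param_state(beta = c(500, -1000), u = rep(0, K))
  expect_true(is.finite(log_likelihood(th_ex, d)))

  expect_error(log_likelihood(param_state(beta = 0, u = rep(0, K)), d),
               "conformable")
})

test_that("penalty priors match their closed forms and moments", {
  expect_equal(laplace_logprior(0, 1), log(1 / 2))
  expect_equal(laplace_logprior(1, 1), -1 - log(2))
  expect_error(laplace_logprior(1, 0), "positive")

  # Laplace(0, tau) has variance 2 tau^2: Monte-Carlo at 1e6 draws,
  # 3-sigma band for the variance estimator (sd ~= sqrt(20 tau^4 / n))
  set.seed(19)
  tau <- 1.3
  v <- var(rlaplace(1e6, tau))
  expect_lt(abs(v - 2 * tau^2), 3 * sqrt(20 * tau^4 / 1e6))

  expect_equal(normal_logprior(0, 1), -0.5 * log(2 * pi))
  for (s in c(0.4, 2)) {
    expect_equal(normal_logprior(s, s), -0.5 * log(2 * pi * s^2) - 0.5)
  }
  set.seed(20)
  u <- rnorm(3)
  expect_equal(normal_logprior(u, 1.7), sum(dnorm(u, 0, 1.7, log = TRUE)))
  expect_error(normal_logprior(1, -1), "positive")
})

test_that("variance-component hyperpriors have the right support and mass", {
  su <- spmm_spec("lasso", gamma_prior = "uniform")
  expect_identical(gamma_logprior(150, su), -Inf)
  expect_identical(gamma_logprior(50, su), 0)

  sh <- spmm_spec("lasso", gamma_prior = "half_cauchy", hc_scale = 25)
  expect_equal(gamma_logprior(0, sh), log(2 / (25 * pi)))
  expect_identical(gamma_logprior(-1, sh), -Inf)

  # the normalized half-Cauchy integrates to 1 over (0, Inf)
  mass <- integrate(function(g) exp(vapply(g, gamma_logprior, numeric(1), sh)),
                    0, Inf, rel.tol = 1e-9)$value
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("log posterior is the sum of its four components", {
  d <- toy_data(n = 30, K = 4, seed = 6)
  set.seed(21)
  for (pen in c("lasso", "ridge")) {
    spec <- spmm_spec(pen, gamma_prior = "half_cauchy")
    th <- param_state(beta = rnorm(2), u = rnorm(4), gamma = runif(1, 0.5, 3))
    up <- if (pen == "lasso") laplace_logprior(th$u, th$gamma) else
      normal_logprior(th$u, th$gamma)
    expect_equal(
      log_posterior(th, d, spec),
      log_likelihood(th, d) +
        sum(dnorm(th$beta, 0, sqrt(spec$beta_prior_var), log = TRUE)) +
        up + gamma_logprior(th$gamma, spec))
  }
})

test_that("posterior differences at fixed gamma reproduce the penalized likelihoods", {
  # lambda = 1/tau (L1) and lambda = 1/(2 sigma^2) (L2); the fixed-effect and
  # hyperprior terms cancel in the difference when the states share beta
  d <- toy_data(n = 30, K = 4, seed = 9)
  set.seed(22)
  for (rep in 1:20) {
    beta <- rnorm(2)
    g <- runif(1, 0.3, 4)
    th1 <- param_state(beta, u = rnorm(4), gamma = g)
    th2 <- param_state(beta, u = rnorm(4), gamma = g)

    sl <- spmm_spec("lasso")
    dl <- log_posterior(th1, d, sl) - log_posterior(th2, d, sl)
    pl <- penalized_loglik(th1, 1 / g, "lasso", d) -
      penalized_loglik(th2, 1 / g, "lasso", d)
    expect_equal(dl, pl, tolerance = 1e-12)

    sr <- spmm_spec("ridge")
    dr <- log_posterior(th1, d, sr) - log_posterior(th2, d, sr)
    pr <- penalized_loglik(th1, 1 / (2 * g^2), "ridge", d) -
      penalized_loglik(th2, 1 / (2 * g^2), "ridge", d)
    expect_equal(dr, pr, tolerance = 1e-12)
  }
})

test_that("penalized log likelihood degenerates and hand-computes correctly", {
  d <- toy_data(n = 30, K = 4, seed = 10)
  set.seed(23)
  th <- param_state(beta = rnorm(2), u = rnorm(4))
  expect_equal(penalized_loglik(th, 0, "lasso", d), log_likelihood(th, d))
  th0 <- param_state(beta = th$beta, u = rep(0, 4))
  expect_equal(penalized_loglik(th0, 3.7, "ridge", d), log_likelihood(th0, d))
  expect_error(penalized_loglik(th, -1, "lasso", d), "nonnegative")

  # 3-observation case, every term written out by hand
  X <- cbind(1, c(0.1, 0.5, 0.9))
  Z <- matrix(c(0.2, 0, 0.1, 0.3, 0.4, 0), 3, 2)
  d3 <- spmm_data(y = c(1, 0, 1), x = c(0.1, 0.5, 0.9),
                  design = structure(list(X = X, Z = Z, blocks = c(1L, 1L)),
                                     class = "spmm_design"))
  th3 <- param_state(beta = c(0.5, -1), u = c(2, -3))
  eta <- drop(X %*% th3$beta + Z %*% th3$u)
  manual <- -sum((1 - c(1, 0, 1)) * eta + log(1 + exp(-eta))) - 0.8 * (2 + 3)
  expect_equal(penalized_loglik(th3, 0.8, "lasso", d3), manual)
})

test_that("additive designs center each smoother block", {
  set.seed(30)
  n <- 150
  df <- data.frame(y = rbinom(n, 1, 0.5), x1 = runif(n), x2 = rnorm(n),
                   z = rbinom(n, 1, 0.4))

  # one smooth term, no fixed terms: lrtp design plus centering
  d1 <- build_additive_design(df, "y", list(x1 = basis_spec("lrtp", K = 4)))
  ref <- lrtp_design(df$x1, place_knots(df$x1, 4))
  expect_equal(unname(d1$design$X[, 2]), df$x1)
  expect_equal(d1$design$Z,
               scale(ref$Z, center = TRUE, scale = FALSE),
               ignore_attr = TRUE)

  # two smoothers with K = 3: two blocks of 3 mean-zero columns
  d2 <- build_additive_design(df, "y",
                              list(x1 = basis_spec("lrtp", K = 3),
                                   x2 = basis_spec("lrtp", K = 3)),
                              fixed_terms = "z")
  expect_identical(ncol(d2$design$Z), 6L)
  expect_identical(d2$design$blocks, rep(1:2, each = 3L))
  expect_lt(max(abs(colMeans(d2$design$Z))), 1e-12)
  expect_true("z" %in% colnames(d2$design$X))

  df$const <- 1
  expect_error(
    build_additive_design(df, "y", list(const = basis_spec("lrtp", K = 3))),
    "constant covariate")
  df$z2 <- df$z
  expect_warning(
    build_additive_design(df, "y", list(x1 = basis_spec("lrtp", K = 3)),
                          fixed_terms = c("z", "z2")),
    "collinear")
})
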