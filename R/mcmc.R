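#' MCMC protocol configuration
#'
#' Defaults follow the full protocol used for data analyses: 55,000
#' iterations, 5,000 burn-in, retaining every 50th draw. Simulation studies
#' use the reduced protocol (see \code{\link{sim_config}}).
#'
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations discarded.
#' @param thin Keep every \code{thin}-th iteration after burn-in.
#' @param n_chains Number of chains (1 for simulations, 2 for data analyses).
#' @param seed Master seed; spawns per-chain streams.
#' @export
mcmc_config <- function(n_iter = 55000, burn_in = 5000, thin = 50,
                        n_chains = 1, seed = 1) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

penalty_code <- function(spec) if (spec$penalty == "lasso") 1L else 0L
gprior_code <- function(spec) if (spec$gamma_prior == "uniform") 0L else 1L

# ridge-stabilized logistic fit for chain initialization
init_beta <- function(y, X) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  b <- if (is.null(fit)) rep(0, ncol(X)) else fit$coefficients
  b[!is.finite(b)] <- 0
  pmax(pmin(b, 10), -10)  # cap separation blow-ups
}

#' Fit a penalized-spline logistic mixed model by MCMC
#'
#' Blocked Gibbs sampler: Polya-Gamma data augmentation makes the
#' coefficient vector (beta, u) conditionally Gaussian; the Laplace prior is
#' handled through its exponential scale-mixture representation
#' (conditionally inverse-Gaussian auxiliary updates); each variance
#' component is updated by slice sampling under its Uniform(0, 100) or
#' half-Cauchy prior. Deterministic given the seed in \code{mcmc}.
#'
#' @param data An \code{\link{spmm_data}}; if its design is NULL a
#'   single-smoother design is built from \code{spec$basis}.
#' @param spec An \code{\link{spmm_spec}}.
#' @param mcmc An \code{\link{mcmc_config}}.
#' @param gamma_fixed Optional fixed value(s) of the variance-component scale
#'   (one per smoother block); when supplied gamma is not sampled.
#' @param prior_only If TRUE the likelihood is switched off and the chain
#'   targets the joint prior (used for prior-recovery checks).
#' @return An object of class \code{"spmm_fit"} with elements \code{draws}
#'   (per chain: \code{theta} matrix with named columns, \code{gamma},
#'   \code{a}), \code{curve_draws} (pooled draws of the fitted logit curve at
#'   the data points), \code{summaries}, \code{curve_summary},
#'   \code{diagnostics} and metadata.
#' @export
fit_spmm <- function(data, spec, mcmc = mcmc_config(), gamma_fixed = NULL,
                     prior_only = FALSE) {
  stopifnot(inherits(data, "spmm_data"), inherits(spec, "spmm_spec"))
  if (is.null(data$design)) {
    data$design <- build_design(data$x, spec$basis)
  }
  des <- data$design
  X <- des$X; Z <- des$Z
  n <- length(data$y); K <- ncol(Z); p <- ncol(X)
  if (!prior_only && n < K + 5) {
    warning("sample size below K + 5; fit may be unstable")
  }
  B <- max(des$blocks)
  gf <- if (is.null(gamma_fixed)) numeric(0) else {
    if (length(gamma_fixed) == 1) rep(gamma_fixed, B) else gamma_fixed
  }

  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, mcmc$n_chains)

  pnames <- c(colnames(X), paste0("u", seq_len(K)))
  if (is.null(colnames(X))) {
    pnames <- c(c("(Intercept)", paste0("x", seq_len(p - 1))),
                paste0("u", seq_len(K)))
  }

  b0 <- if (prior_only) rep(0, p) else init_beta(data$y, X)
  chains <- vector("list", mcmc$n_chains)
  for (cc in seq_len(mcmc$n_chains)) {
    set.seed(chain_seeds[cc])
    # dispersed starting points beyond the first chain
    binit <- if (cc == 1) b0 else b0 + stats::rnorm(p, 0, 1)
    ginit <- if (cc == 1) 1 else stats::runif(1, 0.2, 5)
    res <- gibbs_spmm(data$y, X, Z, des$blocks, penalty_code(spec),
                      gprior_code(spec), spec$hc_scale, spec$beta_prior_var,
                      gf, prior_only, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      binit, ginit)
    colnames(res$theta) <- pnames
    colnames(res$gamma) <- paste0("gamma", seq_len(B))
    if (length(gf) == 0 && spec$gamma_prior == "uniform" &&
        any(res$boundary_count > 0.5 * mcmc$n_iter)) {
      warning("gamma pinned at prior boundary for > 50% of iterations")
    }
    chains[[cc]] <- res
  }

  theta_all <- do.call(rbind, lapply(chains, `[[`, "theta"))
  gamma_all <- do.call(rbind, lapply(chains, `[[`, "gamma"))
  par_all <- cbind(theta_all, if (length(gf) == 0) gamma_all)

  curve_draws <- theta_all %*% t(cbind(X, Z))  # draws x n logit curve

  summ <- t(apply(par_all, 2, posterior_summary))
  summaries <- tibble::tibble(parameter = rownames(summ),
                              median = summ[, 1], lower = summ[, 2],
                              upper = summ[, 3])
  cs <- t(apply(curve_draws, 2, posterior_summary))
  ord <- seq_len(n)
  curve_summary <- tibble::tibble(
    x = if (is.numeric(data$x)) data$x else NA_real_,
    median = cs[, 1], lower = cs[, 2], upper = cs[, 3])

  diagnostics <- list(boundary_frac = sapply(chains, function(ch)
    max(ch$boundary_count) / mcmc$n_iter))
  if (mcmc$n_chains >= 2) {
    diagnostics$rhat <- vapply(colnames(par_all), function(pn) {
      gelman_rubin(lapply(chains, function(ch) {
        m <- cbind(ch$theta, if (length(gf) == 0) ch$gamma)
        m[, pn]
      }))
    }, numeric(1))
  }

  structure(list(draws = chains, curve_draws = curve_draws,
                 summaries = summaries, curve_summary = curve_summary,
                 diagnostics = diagnostics, data = data, spec = spec,
                 mcmc = mcmc, chain_seeds = chain_seeds,
                 gamma_fixed = gamma_fixed, param_names = colnames(par_all)),
            class = "spmm_fit")
}

#' Pooled posterior draws of a parameter
#'
#' @param fit An \code{spmm_fit}.
#' @param parameter Parameter name as in \code{fit$summaries}.
#' @export
posterior_draws <- function(fit, parameter) {
  unlist(lapply(fit$draws, function(ch) {
    m <- cbind(ch$theta, if (is.null(fit$gamma_fixed)) ch$gamma)
    m[, parameter]
  }), use.names = FALSE)
}

#' Posterior summary: median and central 95% interval
#'
#' Empirical median and the 2.5th/97.5th percentiles (linear interpolation of
#' order statistics).
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @param level Credible level (default 0.95).
#' @return Named vector \code{c(median, lower, upper)}.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  if (length(draws) == 0) stop("empty draws vector")
  al <- (1 - level) / 2
  q <- unname(stats::quantile(draws, c(al, 1 - al), type = 7))
  c(median = stats::median(draws), lower = q[1], upper = q[2])
}

#' Gelman-Rubin potential scale reduction factor (square-root form)
#'
#' Conservative variant \code{sqrt((W + B_n) / W)} where W is the mean
#' within-chain variance and B_n the sample variance of the chain means. It
#' is always >= 1, equals exactly 1 when the chains are identical, and for
#' well-mixed chains of length n is approximately \code{sqrt(1 + 1/n)}.
#' Chains with zero variance everywhere return 1 by convention.
#'
#' @param chains List of >= 2 equal-length numeric vectors (or a matrix with
#'   one chain per column).
#' @return The scalar square-root potential scale reduction factor.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("at least two chains required")
  len <- vapply(chains, length, integer(1))
  if (length(unique(len)) != 1) stop("chains must have equal length")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B_n <- stats::var(vapply(chains, mean, numeric(1)))
  if (W == 0) return(if (B_n == 0) 1 else Inf)
  sqrt((W + B_n) / W)
}

#' Pointwise credible band for the fitted logit curve on a grid
#'
#' Evaluates every retained draw of m(x) = X beta + Z u on \code{grid} and
#' applies \code{\link{posterior_summary}} pointwise. Bands at a lower
#' nominal level are nested inside bands at a higher level.
#'
#' @param fit A single-smoother \code{spmm_fit}.
#' @param grid Numeric vector of covariate values.
#' @param level Credible level.
#' @return Tibble with columns x, median, lower, upper.
#' @export
credible_band <- function(fit, grid, level = 0.95) {
  des <- fit$data$design
  if (des$kind == "additive") stop("use smooth_curve() for additive fits")
  xr <- range(fit$data$x)
  if (any(grid < xr[1]) || any(grid > xr[2])) {
    warning("grid extends beyond the observed covariate range (extrapolation)")
  }
  ev <- eval_design(des, grid)
  theta_all <- do.call(rbind, lapply(fit$draws, `[[`, "theta"))
  cd <- theta_all %*% t(cbind(ev$X, ev$Z))
  cs <- t(apply(cd, 2, posterior_summary, level = level))
  tibble::tibble(x = grid, median = cs[, 1], lower = cs[, 2], upper = cs[, 3])
}

#' Posterior smooth-curve summary for one term of an additive fit
#'
#' Reconstructs the draws of the centered smooth m_j on a grid: the linear
#' part plus the penalized block, re-centered per draw so that the smooth
#' sums to zero over the sample (its level is absorbed by the intercept).
#'
#' @param fit An additive \code{spmm_fit}.
#' @param term Smoothed covariate name.
#' @param grid Grid of covariate values (default: 200 points over the range).
#' @export
smooth_curve <- function(fit, term, grid = NULL) {
  des <- fit$data$design
  if (des$kind != "additive") stop("fit is not an additive model")
  j <- which(vapply(des$smoothers, `[[`, character(1), "var") == term)
  if (length(j) != 1) stop("unknown smooth term: ", term)
  sj <- des$smoothers[[j]]
  xv <- fit$data$x[[term]]
  if (is.null(grid)) grid <- seq(min(xv), max(xv), length.out = 200)
  ev <- eval_design(sj, grid)
  evs <- eval_design(sj, xv)  # for the per-draw centering over the sample
  lin_g <- ev$X[, -1, drop = FALSE]
  lin_s <- evs$X[, -1, drop = FALSE]
  Zg <- sweep(ev$Z, 2, sj$center)
  Zc <- sweep(evs$Z, 2, sj$center)
  lin_names <- paste0(term, c("", "^2")[seq_len(ncol(lin_g))])
  theta_all <- do.call(rbind, lapply(fit$draws, `[[`, "theta"))
  bcols <- match(lin_names, colnames(theta_all))
  ucols <- which(colnames(theta_all) %in%
                   paste0("u", which(des$blocks == j)))
  draws_g <- theta_all[, bcols, drop = FALSE] %*% t(lin_g) +
    theta_all[, ucols, drop = FALSE] %*% t(Zg)
  draws_s <- theta_all[, bcols, drop = FALSE] %*% t(lin_s) +
    theta_all[, ucols, drop = FALSE] %*% t(Zc)
  draws_g <- draws_g - rowMeans(draws_s)
  cs <- t(apply(draws_g, 2, posterior_summary))
  tibble::tibble(x = grid, median = cs[, 1], lower = cs[, 2], upper = cs[, 3])
}

#' Monte-Carlo standard error by batch means
#'
#' @param draws Numeric vector of (possibly autocorrelated) draws.
#' @param n_batches Number of batches.
#' @export
mcse_batch <- function(draws, n_batches = 30) {
  n <- length(draws)
  bs <- floor(n / n_batches)
  if (bs < 2) return(stats::sd(draws) / sqrt(n))
  means <- vapply(seq_len(n_batches), function(b)
    mean(draws[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

#' @export
print.spmm_fit <- function(x, ...) {
  cat("Penalized-spline logistic mixed model (", x$spec$penalty,
      " penalty, ", x$data$design$kind, " basis)\n", sep = "")
  cat("n =", length(x$data$y), " K =", ncol(x$data$design$Z),
      " chains =", x$mcmc$n_chains,
      " retained draws =", nrow(x$curve_draws), "\n\n")
  print(x$summaries, n = 20)
  invisible(x)
}
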