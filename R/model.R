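#' Model specification for a penalized-spline logistic mixed model
#'
#' The spline knot coefficients u_k are treated as random effects. A Laplace
#' (double-exponential) prior with scale tau gives the Bayesian analogue of an
#' L1 (LASSO) penalty with smoothing parameter lambda = 1/tau; a normal prior
#' with standard deviation sigma gives the L2 (ridge) penalty with
#' lambda = 1/(2 sigma^2). The scale gamma (tau or sigma) is the variance
#' component of the mixed-model representation and receives either a
#' Uniform(0, 100) or a half-Cauchy hyperprior.
#'
#' @param penalty \code{"lasso"} or \code{"ridge"}.
#' @param gamma_prior \code{"uniform"} (Uniform(0, 100)) or \code{"half_cauchy"}.
#' @param hc_scale Scale s of the half-Cauchy prior (default 25).
#' @param beta_prior_var Variance of the independent normal priors on fixed
#'   effects (default 1e6, effectively noninformative).
#' @param basis A \code{\link{basis_spec}}.
#' @return An object of class \code{"spmm_spec"}.
#' @export
spmm_spec <- function(penalty = c("lasso", "ridge"),
                      gamma_prior = c("uniform", "half_cauchy"),
                      hc_scale = 25, beta_prior_var = 1e6,
                      basis = basis_spec()) {
  penalty <- match.arg(penalty)
  gamma_prior <- match.arg(gamma_prior)
  if (hc_scale <= 0) stop("half-Cauchy scale must be positive")
  if (beta_prior_var <= 0) stop("beta_prior_var must be positive")
  structure(list(penalty = penalty, gamma_prior = gamma_prior,
                 hc_scale = hc_scale, beta_prior_var = beta_prior_var,
                 basis = basis),
            class = "spmm_spec")
}

#' Parameter state of the model
#'
#' @param beta Fixed-effect vector.
#' @param u Knot-coefficient vector (length K, may be length 0).
#' @param gamma Positive variance-component scale(s), one per smoother block.
#' @export
param_state <- function(beta, u = numeric(0), gamma = 1) {
  if (any(gamma <= 0)) stop("gamma must be positive")
  structure(list(beta = beta, u = u, gamma = gamma), class = "param_state")
}

#' Binary dataset container
#'
#' @param y 0/1 outcome vector.
#' @param x Covariate vector (or data frame of covariates for additive models).
#' @param design An \code{spmm_design}, or NULL to be built at fit time.
#' @export
spmm_data <- function(y, x, design = NULL) {
  if (!all(y %in% c(0, 1))) stop("outcome must contain only 0 and 1")
  nx <- if (is.data.frame(x)) nrow(x) else length(x)
  if (length(y) != nx) stop("outcome and covariate lengths differ")
  if (!is.null(design) && nrow(design$X) != length(y)) {
    stop("design rows do not match outcome length")
  }
  structure(list(y = as.numeric(y), x = x, design = design), class = "spmm_data")
}

# numerically safe log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37
  mid <- !lo & x <= 18
  hi2 <- x > 18 & x <= 33.3
  top <- x > 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi2] <- x[hi2] + exp(-x[hi2])
  out[top] <- x[top]
  out
}

linear_predictor <- function(theta, data) {
  d <- data$design
  eta <- drop(d$X %*% theta$beta)
  if (length(theta$u)) eta <- eta + drop(d$Z %*% theta$u)
  eta
}

#' Success probabilities under a parameter state
#'
#' The inverse-logit of the linear predictor \code{X beta + Z u}.
#' @param theta A \code{\link{param_state}}.
#' @param data An \code{\link{spmm_data}} with design matrices.
#' @export
success_prob <- function(theta, data) {
  stats::plogis(linear_predictor(theta, data))
}

#' Bernoulli-logit log likelihood
#'
#' \code{-sum[(1 - y_i) eta_i + log(1 + exp(-eta_i))]} with
#' \code{eta = X beta + Z u}, evaluated with overflow-safe arithmetic.
#'
#' @inheritParams success_prob
#' @return The log likelihood (scalar).
#' @export
log_likelihood <- function(theta, data) {
  if (ncol(data$design$X) != length(theta$beta) ||
      ncol(data$design$Z) != length(theta$u)) {
    stop("parameter state not conformable with design matrices")
  }
  eta <- linear_predictor(theta, data)
  -sum((1 - data$y) * eta + log1pexp(-eta))
}

#' Laplace (double-exponential) log prior on knot coefficients
#'
#' Density \code{f(u | tau) = exp(-|u|/tau) / (2 tau)} per coefficient;
#' mean 0, variance \code{2 tau^2}. The Bayesian analogue of the LASSO
#' penalty with lambda = 1/tau.
#'
#' @param u Coefficient vector.
#' @param tau Positive scale.
#' @export
laplace_logprior <- function(u, tau) {
  if (tau <= 0) stop("tau must be positive")
  sum(-log(2 * tau) - abs(u) / tau)
}

#' Normal log prior on knot coefficients
#'
#' The Bayesian analogue of the ridge penalty with lambda = 1/(2 sigma^2).
#'
#' @param u Coefficient vector.
#' @param sigma Positive standard deviation.
#' @export
normal_logprior <- function(u, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  sum(stats::dnorm(u, 0, sigma, log = TRUE))
}

#' Log hyperprior on a variance-component scale
#'
#' Uniform(0, 100): 0 inside the support, -Inf outside. Half-Cauchy with
#' scale s: the proper density \code{2 / (pi s (1 + (gamma/s)^2))} so that
#' log-posterior values are comparable across priors.
#'
#' @param gamma Positive scale value.
#' @param spec An \code{\link{spmm_spec}} naming the prior.
#' @export
gamma_logprior <- function(gamma, spec) {
  if (spec$gamma_prior == "uniform") {
    if (gamma > 0 && gamma < 100) 0 else -Inf
  } else {
    if (gamma < 0) return(-Inf)
    s <- spec$hc_scale
    log(2 / (pi * s * (1 + (gamma / s)^2)))
  }
}

#' Joint log posterior (up to a constant)
#'
#' Likelihood plus normal priors on the fixed effects, the penalty prior on
#' the knot coefficients (Laplace or normal according to the spec), and the
#' hyperprior on gamma.
#'
#' @inheritParams success_prob
#' @param spec An \code{\link{spmm_spec}}.
#' @export
log_posterior <- function(theta, data, spec) {
  lp_u <- if (length(theta$u) == 0) 0 else {
    g <- theta$gamma[data$design$blocks]
    if (spec$penalty == "lasso") {
      sum(-log(2 * g) - abs(theta$u) / g)
    } else {
      sum(stats::dnorm(theta$u, 0, g, log = TRUE))
    }
  }
  log_likelihood(theta, data) +
    sum(stats::dnorm(theta$beta, 0, sqrt(spec$beta_prior_var), log = TRUE)) +
    lp_u +
    sum(vapply(theta$gamma, gamma_logprior, numeric(1), spec = spec))
}

#' Penalized log likelihood (frequentist form)
#'
#' \code{l(theta) - lambda sum(|u_k|)} (LASSO) or
#' \code{l(theta) - lambda sum(u_k^2)} (ridge). Differences of the log
#' posterior at fixed gamma reproduce differences of this function with
#' lambda = 1/tau (LASSO) or lambda = 1/(2 sigma^2) (ridge).
#'
#' @inheritParams success_prob
#' @param lambda Nonnegative smoothing parameter.
#' @param penalty \code{"lasso"} or \code{"ridge"}.
#' @export
penalized_loglik <- function(theta, lambda, penalty = c("lasso", "ridge"), data) {
  penalty <- match.arg(penalty)
  if (lambda < 0) stop("lambda must be nonnegative")
  pen <- if (penalty == "lasso") sum(abs(theta$u)) else sum(theta$u^2)
  log_likelihood(theta, data) - lambda * pen
}

#' Build design matrices for an additive model with several smoothers
#'
#' Each smooth term contributes its linear (and, for truncated quadratic,
#' quadratic) part to the fixed-effects matrix and a block of penalized
#' columns to Z. Every Z block is column-centered so that each smoother sums
#' to zero over the sample, resolving the identifiability overlap between the
#' smoothers' levels and the global intercept; each block carries its own
#' variance component.
#'
#' @param data A data frame.
#' @param outcome Name of the 0/1 outcome column.
#' @param smooth_terms Named list: covariate name -> \code{\link{basis_spec}}
#'   (or a character vector of covariate names, all with the default basis).
#' @param fixed_terms Character vector of additional fixed-effect columns
#'   (e.g. binary exposures).
#' @return An \code{\link{spmm_data}} whose design has one block per smoother.
#' @export
build_additive_design <- function(data, outcome, smooth_terms,
                                  fixed_terms = character(0)) {
  if (is.character(smooth_terms)) {
    smooth_terms <- stats::setNames(
      replicate(length(smooth_terms), basis_spec(), simplify = FALSE),
      smooth_terms)
  }
  if (length(smooth_terms) < 1) stop("at least one smooth term required")
  y <- data[[outcome]]
  n <- nrow(data)

  Xf <- matrix(1, n, 1)
  colnames(Xf) <- "(Intercept)"
  if (length(fixed_terms)) {
    Ff <- as.matrix(data[fixed_terms])
    if (any(!is.finite(Ff))) stop("non-finite fixed-effect covariates")
    if (qr(cbind(Xf, Ff))$rank < 1 + ncol(Ff)) {
      warning("collinear fixed terms in additive design")
    }
    Xf <- cbind(Xf, Ff)
  }

  Zs <- list(); blocks <- integer(0); designs <- list()
  for (j in seq_along(smooth_terms)) {
    v <- names(smooth_terms)[j]
    xv <- data[[v]]
    if (any(!is.finite(xv))) stop("non-finite covariate in smooth term ", v)
    if (length(unique(xv)) == 1) stop("constant covariate in smooth term ", v)
    dj <- build_design(xv, smooth_terms[[j]])
    lin <- dj$X[, -1, drop = FALSE]  # drop the per-smoother intercept
    colnames(lin) <- paste0(v, c("", "^2")[seq_len(ncol(lin))])
    Xf <- cbind(Xf, lin)
    Zj <- scale(dj$Z, center = TRUE, scale = FALSE)
    Zs[[j]] <- Zj
    blocks <- c(blocks, rep(j, ncol(Zj)))
    dj$center <- attr(Zj, "scaled:center")
    dj$var <- v
    designs[[j]] <- dj
  }
  Z <- do.call(cbind, Zs)
  des <- new_design(X = Xf, Z = Z, knots = lapply(designs, `[[`, "knots"),
                    transform = NULL, kind = "additive", blocks = blocks)
  des$smoothers <- designs
  des$fixed_terms <- fixed_terms
  spmm_data(y = y, x = data, design = des)
}
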