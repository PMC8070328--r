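#' Choose the number of spline knots by Wand's rule
#'
#' Returns \code{min(floor(u/4), 35)} where \code{u} is the number of unique
#' covariate values, the standard default for low-rank smoothers.
#'
#' @param x Numeric covariate vector.
#' @return A positive integer number of knots.
#' @examples
#' wand_K(seq(0, 1, length.out = 200))  # capped at 35
#' @export
wand_K <- function(x) {
  if (length(x) == 0) stop("empty covariate vector")
  if (any(!is.finite(x))) stop("non-finite covariate values")
  K <- min(floor(length(unique(x)) / 4), 35L)
  if (K < 1) stop("K must be >= 1; too few unique covariate values")
  as.integer(K)
}

#' Place spline knots at sample quantiles of the unique covariate values
#'
#' Knot \code{k} is placed at the \code{(k+1)/(K+2)}-th sample quantile of the
#' unique values of \code{x} (linear interpolation of order statistics,
#' \code{\link[stats]{quantile}} type 7), so the knots partition the observed
#' covariate into roughly even groups while staying away from the extremes.
#'
#' @param x Numeric covariate vector with at least \code{K + 2} unique values.
#' @param K Number of knots (positive integer).
#' @return An object of class \code{"knot_set"}: list with \code{knots}
#'   (strictly increasing numeric vector) and \code{K}.
#' @export
place_knots <- function(x, K) {
  if (any(!is.finite(x))) stop("non-finite covariate values")
  K <- as.integer(K)
  if (length(K) != 1 || is.na(K) || K < 1) stop("K must be a positive integer")
  ux <- sort(unique(x))
  if (length(ux) < K + 2) stop("insufficient unique covariate values")
  probs <- (seq_len(K) + 1) / (K + 2)
  kn <- unname(stats::quantile(ux, probs = probs, type = 7))
  if (any(diff(kn) <= 0)) {
    stop("tied knots after quantile computation; reduce K")
  }
  structure(list(knots = kn, K = K), class = "knot_set")
}

#' Cubic distance penalty matrix for low-rank thin-plate splines
#'
#' The (i, k) entry is \code{|t_i - t_k|^3}; symmetric with zero diagonal.
#'
#' @param knots A \code{knot_set}.
#' @return A K x K numeric matrix.
#' @export
omega_matrix <- function(knots) {
  t <- knots$knots
  abs(outer(t, t, "-"))^3
}

#' Symmetric inverse square root of a symmetric matrix via SVD
#'
#' Computes \code{U diag(d^{-1/2}) V'} from the SVD \code{M = U diag(d) V'}.
#' For a positive-definite \code{M} the result \code{R} satisfies
#' \code{R M R = I}; the SVD form remains well defined for the indefinite
#' cubic-distance penalty matrix of low-rank thin-plate splines.
#'
#' @param M Symmetric numeric matrix.
#' @param tol Relative singular-value tolerance below which \code{M} is
#'   declared singular.
#' @return The inverse square root matrix.
#' @export
matrix_inv_sqrt <- function(M, tol = 1e-10) {
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("M must be symmetric")
  s <- svd(M)
  if (any(s$d < tol * max(s$d))) {
    stop("penalty matrix singular; reduce K or jitter knots")
  }
  s$u %*% (t(s$v) / sqrt(s$d))
}

new_design <- function(X, Z, knots, transform, kind, blocks = rep(1L, ncol(Z))) {
  structure(list(X = X, Z = Z, knots = knots, transform = transform,
                 kind = kind, blocks = as.integer(blocks)),
            class = "spmm_design")
}

#' Low-rank thin-plate spline design matrices
#'
#' Builds the fixed-effects matrix \code{X = [1, x]} and the penalized basis
#' \code{Z = C Omega^{-1/2}} where \code{C[i,k] = |x_i - t_k|^3} and
#' \code{Omega[i,k] = |t_i - t_k|^3}. The transform whitens the cubic basis so
#' that i.i.d. priors on the knot coefficients correspond to the thin-plate
#' roughness penalty, and it markedly improves MCMC mixing.
#'
#' @param x Numeric covariate vector.
#' @param knots A \code{knot_set}.
#' @return An \code{spmm_design}: list with \code{X}, \code{Z}, \code{knots},
#'   \code{transform} (the K x K inverse square root) and \code{kind}.
#' @export
lrtp_design <- function(x, knots) {
  omega <- omega_matrix(knots)
  tr <- matrix_inv_sqrt(omega)
  C <- abs(outer(x, knots$knots, "-"))^3
  new_design(X = cbind(1, x, deparse.level = 0), Z = C %*% tr,
             knots = knots, transform = tr, kind = "lrtp")
}

#' Truncated quadratic spline design matrices
#'
#' \code{X = [1, x, x^2]}, \code{Z[i,k] = max(x_i - t_k, 0)^2}; the penalty
#' transform is the identity.
#'
#' @inheritParams lrtp_design
#' @export
truncated_quadratic_design <- function(x, knots) {
  Z <- pmax(outer(x, knots$knots, "-"), 0)^2
  new_design(X = cbind(1, x, x^2, deparse.level = 0), Z = Z,
             knots = knots, transform = diag(knots$K), kind = "truncated_quadratic")
}

#' Natural (restricted) cubic spline design matrices
#'
#' Restricted-cubic closed form with boundary knots at the first and last
#' knots: each of the K - 2 penalized columns is a combination of truncated
#' cubes that is exactly linear outside \code{[t_1, t_K]}.
#' \code{X = [1, x]}; the transform is the identity.
#'
#' @inheritParams lrtp_design
#' @export
natural_cubic_design <- function(x, knots) {
  t <- knots$knots
  K <- knots$K
  if (K < 3) stop("natural cubic basis requires K >= 3 knots")
  tK <- t[K]; tK1 <- t[K - 1]
  pc <- function(v) pmax(v, 0)^3
  Z <- vapply(seq_len(K - 2), function(k) {
    pc(x - t[k]) -
      pc(x - tK1) * (tK - t[k]) / (tK - tK1) +
      pc(x - tK) * (tK1 - t[k]) / (tK - tK1)
  }, numeric(length(x)))
  Z <- matrix(Z, nrow = length(x))
  new_design(X = cbind(1, x, deparse.level = 0), Z = Z,
             knots = knots, transform = diag(K - 2L), kind = "natural_cubic")
}

#' Basis specification
#'
#' @param kind One of \code{"lrtp"}, \code{"truncated_quadratic"},
#'   \code{"natural_cubic"}.
#' @param K Number of knots, or \code{"wand_rule"} to apply \code{\link{wand_K}}
#'   to the data at design-build time.
#' @export
basis_spec <- function(kind = c("lrtp", "truncated_quadratic", "natural_cubic"),
                       K = "wand_rule") {
  kind <- match.arg(kind)
  if (!identical(K, "wand_rule")) {
    K <- as.integer(K)
    if (is.na(K) || K < 1) stop("K must be a positive integer or \"wand_rule\"")
  }
  structure(list(kind = kind, K = K), class = "basis_spec")
}

#' Build design matrices for one smoother from a basis specification
#'
#' @param x Numeric covariate vector.
#' @param basis A \code{\link{basis_spec}}.
#' @return An \code{spmm_design}.
#' @export
build_design <- function(x, basis = basis_spec()) {
  stopifnot(inherits(basis, "basis_spec"))
  K <- if (identical(basis$K, "wand_rule")) wand_K(x) else basis$K
  kn <- place_knots(x, K)
  switch(basis$kind,
    lrtp = lrtp_design(x, kn),
    truncated_quadratic = truncated_quadratic_design(x, kn),
    natural_cubic = natural_cubic_design(x, kn))
}

# Evaluate the penalized basis columns (and the fixed-effect polynomial part)
# of an existing design at new covariate values.
eval_design <- function(design, xnew) {
  t <- design$knots$knots
  switch(design$kind,
    lrtp = {
      C <- abs(outer(xnew, t, "-"))^3
      list(X = cbind(1, xnew, deparse.level = 0), Z = C %*% design$transform)
    },
    truncated_quadratic = list(
      X = cbind(1, xnew, xnew^2, deparse.level = 0),
      Z = pmax(outer(xnew, t, "-"), 0)^2),
    natural_cubic = {
      d <- natural_cubic_design(xnew, design$knots)
      list(X = d$X, Z = d$Z)
    })
}
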