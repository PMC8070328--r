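#' Benchmark test functions for synthetic dose-response curves
#'
#' Three shapes of association on [0, 1]: \code{"linear"} = log(3) x,
#' \code{"concave"} = sin(pi x), and \code{"double_hump"} =
#' (1/10) \{6 x^29 (1-x)^16 / B(30,17) + 4 x^2 (1-x)^10 / B(3,11)\} with B the
#' Beta function.
#'
#' @param name Test function name.
#' @param x Values in [0, 1].
#' @return The raw (unscaled) function values.
#' @export
test_function_raw <- function(name = c("linear", "concave", "double_hump"), x) {
  name <- match.arg(name)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  switch(name,
    linear = log(3) * x,
    concave = sin(pi * x),
    double_hump = 0.1 * (6 * x^29 * (1 - x)^16 / beta(30, 17) +
                           4 * x^2 * (1 - x)^10 / beta(3, 11)))
}

#' Calibrate a test function onto the logit scale
#'
#' Finds the affine map m(x) = a + b raw(x), b > 0, under which (i) the
#' overall prevalence of a positive outcome under x ~ U(0, 1),
#' \code{integral of expit(m(x)) dx}, equals 0.5 exactly, and (ii) the
#' success probability stays inside [0.02, 0.98] with the largest possible
#' gain b, so the binding endpoint of that range is attained exactly. For a
#' shape whose raw values are symmetrically distributed (the linear one) both
#' endpoints 0.02 and 0.98 are attained; for asymmetric shapes one endpoint
#' binds (0.02 for the concave hump, 0.98 for the double hump). The raw range
#' is located on a deterministic 10,001-point grid; prevalence is evaluated
#' by adaptive quadrature and the constraint solved by root-finding.
#'
#' @param name Test function name.
#' @return An object of class \code{"test_function"}: list with \code{name},
#'   \code{raw} and \code{scaled} functions, \code{scale_params} (a, b) and
#'   the achieved \code{prevalence}.
#' @export
calibrate_function <- function(name = c("linear", "concave", "double_hump")) {
  name <- match.arg(name)
  grid <- seq(0, 1, length.out = 10001)
  r <- test_function_raw(name, grid)
  rmin <- min(r); rmax <- max(r)
  if (rmax - rmin < 1e-12) stop("constant test function cannot be calibrated")
  lo <- stats::qlogis(0.02); hi <- stats::qlogis(0.98)

  prevalence <- function(a, b) {
    stats::integrate(function(x) stats::plogis(a + b * test_function_raw(name, x)),
                     0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  # offset keeping prevalence at 0.5 for a given gain (prevalence is
  # strictly increasing in a)
  a_of_b <- function(b) {
    stats::uniroot(function(a) prevalence(a, b) - 0.5,
                   lower = -20, upper = 20, tol = 1e-12)$root
  }
  # slack of the two range constraints; both positive at small b, the
  # binding one crosses zero as b grows
  slack <- function(b) {
    a <- a_of_b(b)
    min(a + b * rmin - lo, hi - (a + b * rmax))
  }
  b_sym <- (hi - lo) / (rmax - rmin)
  b <- stats::uniroot(slack, lower = 1e-6, upper = 3 * b_sym,
                      tol = 1e-10)$root
  a <- a_of_b(b)

  raw_fn <- function(x) test_function_raw(name, x)
  scaled_fn <- function(x) a + b * test_function_raw(name, x)
  structure(list(name = name, raw = raw_fn, scaled = scaled_fn,
                 scale_params = c(a = a, b = b),
                 prevalence = prevalence(a, b)),
            class = "test_function")
}

#' Generate a synthetic binary dataset from a calibrated test function
#'
#' Covariates are i.i.d. U(0, 1); outcomes are Bernoulli with
#' logit P(Y = 1 | x) = m(x), the calibrated logit curve. Deterministic given
#' the seed.
#'
#' @param fn A \code{\link{calibrate_function}} result.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return An \code{\link{spmm_data}} with extra fields \code{m_true} and
#'   \code{p_true}.
#' @export
generate_dataset <- function(fn, n = 500, seed = 1) {
  stopifnot(inherits(fn, "test_function"))
  set.seed(seed)
  x <- stats::runif(n)
  m <- fn$scaled(x)
  p <- stats::plogis(m)
  y <- stats::rbinom(n, 1, p)
  d <- spmm_data(y = y, x = x)
  d$m_true <- m
  d$p_true <- p
  d$fn_name <- fn$name
  d$seed <- seed
  d
}
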