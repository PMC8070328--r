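#' Average squared error of an estimated curve
#'
#' \code{ASE = mean((m_hat - m_true)^2)} over the evaluation points.
#'
#' @param m_hat Estimated curve values.
#' @param m_true True curve values.
#' @export
ase <- function(m_hat, m_true) {
  if (length(m_hat) != length(m_true)) stop("length mismatch")
  mean((m_hat - m_true)^2)
}

#' Average coverage probability and average interval length
#'
#' \code{ACP = mean(1(lower < m_true < upper))} with strict inequalities
#' (a truth exactly on a bound counts as non-covered);
#' \code{ACL = mean(upper - lower)}.
#'
#' @param m_true True curve values.
#' @param lower,upper Pointwise interval bounds, \code{lower <= upper}.
#' @return Named vector \code{c(acp, acl)}.
#' @export
acp_acl <- function(m_true, lower, upper) {
  if (length(m_true) != length(lower) || length(lower) != length(upper)) {
    stop("length mismatch")
  }
  if (any(lower > upper)) stop("crossed interval bounds")
  c(acp = mean(lower < m_true & m_true < upper),
    acl = mean(upper - lower))
}

#' Index sets for the boundary strips of the covariate
#'
#' Lower strip: \code{x < min(x) + fraction * range(x)}; upper strip:
#' \code{x > max(x) - fraction * range(x)} (range-based, default 10%).
#'
#' @param x Covariate vector with positive range.
#' @param fraction Strip width as a fraction of the range.
#' @return List with integer index vectors \code{lower} and \code{upper}.
#' @export
boundary_slice <- function(x, fraction = 0.10) {
  r <- range(x)
  if (diff(r) <= 0) stop("constant covariate has no boundary strips")
  list(lower = which(x < r[1] + fraction * diff(r)),
       upper = which(x > r[2] - fraction * diff(r)))
}
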