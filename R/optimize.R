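# One-dimensional bounded maximization used for pendant-length and rate
# optimization.

#' Maximize a unimodal objective over one positive parameter
#'
#' Golden-section/parabolic refinement via [stats::optimize()], with the
#' bracket endpoints also evaluated so boundary optima are returned
#' (unimodality is a contract, not checked).
#'
#' @param f Objective taking a scalar and returning a scalar.
#' @param lower,upper Bracket.
#' @param tol Relative tolerance (default 1e-6).
#' @return List with `par` (argmax) and `value` (maximum).
#' @export
optimize_scalar <- function(f, lower, upper, tol = 1e-6) {
  stopifnot(lower < upper)
  fl <- f(lower); fu <- f(upper)
  if (!is.finite(fl) && !is.finite(fu))
    stop("objective non-finite at both bounds")
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE,
                         tol = tol * max(1, abs(upper)))
  cand_par <- c(opt$maximum, lower, upper)
  cand_val <- c(opt$objective, fl, fu)
  cand_val[!is.finite(cand_val)] <- -Inf
  best <- which.max(cand_val)
  list(par = cand_par[best], value = cand_val[best])
}
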