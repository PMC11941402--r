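#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain -Inf).
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
#' @noRd
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Deterministic child seed for replicate r under a root seed
#'
#' Replicate-level results are individually reproducible: replicate `r` of an
#' experiment with root seed `root` always uses `child_seed(root, r)`.
#' Implemented as a Lehmer-style mix kept below 2^31.
#'
#' @param root integer root seed.
#' @param r replicate index (>= 0).
#' @return an integer seed in 1..2147483646.
#' @export
child_seed <- function(root, r) {
  root <- abs(as.numeric(root)) %% 2147483647
  v <- (root * 48271 + as.numeric(r) * 16807 + 12345) %% 2147483646
  as.integer(v + 1)
}

## parameter transforms: positive parameters handled on the log scale during
## optimisation and MCMC; beta / mu stay natural.
positive_params <- c("sigma1", "sigma2", "sigma2_obs", "tau2")

to_transformed <- function(theta, names) {
  v <- theta[names]
  pos <- names %in% positive_params
  v[pos] <- log(v[pos])
  v
}

from_transformed <- function(v, names, theta_base) {
  pos <- names %in% positive_params
  v[pos] <- exp(v[pos])
  theta_base[names] <- v
  theta_base
}

## delta-method scale factor d(natural)/d(transformed) at a point
transform_jacobian <- function(theta, names) {
  j <- rep(1, length(names))
  pos <- names %in% positive_params
  j[pos] <- theta[names[pos]]
  j
}
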