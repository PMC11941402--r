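## all per-observation exact bias factors at once (internal workhorse)
bias_factors_exact <- function(spec, theta, data, cfg = quad_config()) {
  theta <- check_theta(spec, theta)
  im <- inner_modes(spec, theta, data, inner_config("multistart"))
  ll_i <- obs_marginal_loglik(spec, theta, data, cfg)
  ## log b_i = [log f(y_i, u_hat_i) + 0.5 log 2pi - 0.5 log(-H_i)] - log L_i
  exp(im$objective + 0.5 * log(2 * pi) - 0.5 * log(-im$curvatures) - ll_i)
}

#' Exact per-observation Laplace bias factor
#'
#' The multiplicative error of the Laplace approximation for observation i:
#' \deqn{b_i = f(\hat u_i | y_i, w_i; \theta) \sqrt{2\pi}\,(-H_i)^{-1/2},}
#' with the conditional density evaluated as
#' \eqn{\exp\{\log f(y_i, \hat u_i;\theta) - \ell_i\}} and the exact
#' per-observation marginal \eqn{\ell_i} from the quadrature oracle. The
#' factor equals the ratio of the observation's Laplace likelihood term to
#' its exact marginal term, so \eqn{\sum_i \log b_i} is identically the
#' Laplace-minus-exact log-likelihood gap; it is exactly 1 whenever the
#' conditional latent density is Gaussian.
#'
#' @inheritParams quadrature_loglik
#' @param i observation index.
#' @return positive scalar.
#' @export
bias_factor_exact <- function(spec, theta, data, i, cfg = quad_config()) {
  stopifnot(i >= 1, i <= data$n)
  bias_factors_exact(spec, theta, data_subset(data, i), cfg)
}

## kernel-density estimate of a bias factor from posterior latent draws:
## density height at the KDE mode and curvature of the log-KDE there
kde_mode_bias <- function(draws, bw = "SJ") {
  if (stats::sd(draws) < 1e-10) stop("degenerate draws: near point mass")
  d <- try(stats::density(draws, bw = bw, n = 2048), silent = TRUE)
  if (inherits(d, "try-error")) d <- stats::density(draws, n = 2048)
  i0 <- which.max(d$y)
  mode <- d$x[i0]
  ## the fit window must be wide enough for the quadratic signal to beat the
  ## KDE's wiggle noise (about one SD of the draws); kernel smoothing then
  ## inflates the apparent variance and deflates the peak height by exactly
  ## cancelling factors, so no bandwidth deconvolution is needed
  win <- max(4 * d$bw, stats::sd(draws))
  sel <- which(abs(d$x - mode) <= win & d$y > 0)
  if (length(sel) < 9) sel <- max(1, i0 - 4):min(length(d$x), i0 + 4)
  fit <- stats::lm(log(d$y[sel]) ~ stats::poly(d$x[sel], 2, raw = TRUE),
                   weights = d$y[sel])
  curv <- 2 * unname(stats::coef(fit)[3])
  if (!is.finite(curv) || curv >= 0)
    stop("non-negative curvature of the log-density at its mode")
  list(b = d$y[i0] * sqrt(2 * pi) / sqrt(-curv), mode = mode,
       density_at_mode = d$y[i0], curvature = curv)
}

#' MCMC + kernel-density estimate of a bias factor
#'
#' Replicates the simulation route to the bias factor: sample the
#' conditional latent distribution of observation i by MCMC, estimate the
#' density at its mode and the curvature of the log-density there from a
#' kernel density estimate (Sheather-Jones bandwidth; local quadratic fit to
#' the log-KDE over mode +/- one bandwidth), and combine them as in
#' [bias_factor_exact()]. The standard error is a block bootstrap over
#' contiguous chain blocks.
#'
#' @inheritParams inner_modes
#' @param i observation index.
#' @param cfg a [chain_config()].
#' @param draws optional numeric vector of conditional-latent draws for
#'   observation i (skips the MCMC run).
#' @param n_boot bootstrap replicates for the standard error.
#' @return list with `value`, `se`, and the KDE summaries.
#' @export
bias_factor_mcmc <- function(spec, theta, data, i, cfg = chain_config(),
                             draws = NULL, n_boot = 30) {
  if (is.null(draws)) {
    ch <- suppressWarnings(
      sample_conditional_latent(spec, theta, data_subset(data, i), cfg))
    draws <- ch$draws[, 1]
  }
  est <- kde_mode_bias(draws)
  nb <- 20
  blocks <- split(draws, cut(seq_along(draws), nb, labels = FALSE))
  bs <- replicate(n_boot, {
    idx <- sample.int(nb, nb, replace = TRUE)
    v <- try(kde_mode_bias(unlist(blocks[idx], use.names = FALSE))$b,
             silent = TRUE)
    if (inherits(v, "try-error")) NA_real_ else v
  })
  list(value = est$b, se = stats::sd(bs, na.rm = TRUE),
       mode = est$mode, density_at_mode = est$density_at_mode,
       curvature = est$curvature)
}

#' Bias-factor profile along a slope grid
#'
#' Evaluates the per-observation bias factor for observation `i` along a
#' grid of slope values (other parameters held at `theta_fixed`), exactly
#' via the quadrature route and optionally by the MCMC + KDE route with a
#' LOESS smoother over the noisy MCMC estimates.
#'
#' @inheritParams inner_modes
#' @param i observation index.
#' @param beta_grid grid for the varying parameter.
#' @param parameter name of the varying parameter (default `"beta"`).
#' @param theta_fixed full parameter vector supplying the fixed values.
#' @param with_mcmc also compute the MCMC + KDE estimates.
#' @param quad_cfg,chain_cfg method configurations.
#' @return an object of class `bias_profile` with `beta_grid`, `bias_exact`,
#'   and optionally `bias_mcmc`, `bias_mcmc_se`, `smoother_fit`.
#' @export
bias_profile <- function(spec, data, i, beta_grid, theta_fixed,
                         parameter = "beta", with_mcmc = FALSE,
                         quad_cfg = quad_config(),
                         chain_cfg = chain_config()) {
  theta_fixed <- check_theta(spec, theta_fixed)
  di <- data_subset(data, i)
  b_exact <- vapply(beta_grid, function(p) {
    th <- theta_fixed; th[parameter] <- p
    v <- try(bias_factors_exact(spec, th, di, quad_cfg), silent = TRUE)
    if (inherits(v, "try-error")) NA_real_ else v
  }, 0)
  out <- list(observation_index = i, beta_grid = beta_grid,
              bias_exact = b_exact)
  if (with_mcmc) {
    mc <- lapply(seq_along(beta_grid), function(j) {
      th <- theta_fixed; th[parameter] <- beta_grid[j]
      cfg_j <- chain_cfg; cfg_j$seed <- child_seed(chain_cfg$seed, j)
      v <- try(bias_factor_mcmc(spec, th, data, i, cfg_j, n_boot = 10),
               silent = TRUE)
      if (inherits(v, "try-error")) list(value = NA_real_, se = NA_real_) else v
    })
    out$bias_mcmc <- vapply(mc, `[[`, 0, "value")
    out$bias_mcmc_se <- vapply(mc, `[[`, 0, "se")
    ok <- is.finite(out$bias_mcmc)
    if (sum(ok) >= 8) {
      lo <- stats::loess(out$bias_mcmc[ok] ~ beta_grid[ok], span = 0.75)
      out$smoother_fit <- stats::predict(lo, newdata = beta_grid)
    }
  }
  structure(out, class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  lb <- log(x$bias_exact)
  cat("<bias_profile> observation", x$observation_index, "|",
      length(x$beta_grid), "grid points\n")
  cat("  log b range:", paste(format(range(lb, na.rm = TRUE), digits = 4),
                              collapse = " .. "),
      if (!is.null(x$bias_mcmc)) "| MCMC route included", "\n")
  invisible(x)
}

#' @export
as.data.frame.bias_profile <- function(x, ...) {
  data.frame(observation = x$observation_index, beta = x$beta_grid,
             bias_exact = x$bias_exact,
             bias_mcmc = if (!is.null(x$bias_mcmc)) x$bias_mcmc else NA_real_,
             smoother = if (!is.null(x$smoother_fit)) x$smoother_fit else NA_real_)
}
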