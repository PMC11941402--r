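#' Random-walk Metropolis chain configuration
#'
#' @param iterations total iterations per chain.
#' @param burn_in iterations discarded (and used for proposal adaptation;
#'   the proposal scale is frozen afterwards so the retained draws target the
#'   exact invariant law).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param proposal_sd `"adaptive"` (scale tuned during burn-in towards an
#'   acceptance rate of 0.3-0.5) or a fixed positive number.
#' @param seed integer seed; chain c uses `child_seed(seed, c)`.
#' @param n_chains number of chains (>= 2; convergence diagnostics rely on
#'   cross-chain disagreement).
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(iterations = 6000, burn_in = 1000, thin = 1,
                         proposal_sd = "adaptive", seed = 1, n_chains = 2) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1, n_chains >= 1)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 proposal_sd = proposal_sd, seed = seed, n_chains = n_chains),
            class = "chain_config")
}

## split-chain potential scale reduction and effective size via coda
chain_diagnostics <- function(per_chain) {
  d <- ncol(per_chain[[1]])
  if (length(per_chain) >= 2) {
    ml <- coda::mcmc.list(lapply(per_chain, coda::mcmc))
    rhat <- tryCatch(
      coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
      error = function(e) rep(NA_real_, d))
  } else rhat <- rep(NA_real_, d)
  ess <- tryCatch(as.numeric(coda::effectiveSize(
    coda::mcmc(do.call(rbind, per_chain)))), error = function(e) rep(NA_real_, d))
  list(rhat = rhat, ess = ess)
}

new_chain_output <- function(per_chain, acceptance_rate, proposal_sd,
                             param_names = NULL) {
  per_chain <- lapply(per_chain, function(M) {
    if (!is.null(param_names)) colnames(M) <- param_names
    M
  })
  dg <- chain_diagnostics(per_chain)
  out <- structure(list(draws = do.call(rbind, per_chain),
                        per_chain = per_chain,
                        acceptance_rate = acceptance_rate,
                        proposal_sd = proposal_sd,
                        rhat = dg$rhat, ess = dg$ess),
                   class = "chain_output")
  if (any(is.finite(out$rhat) & out$rhat > 1.05))
    warning("R-hat exceeds 1.05 for dimension(s) ",
            paste(which(out$rhat > 1.05), collapse = ", "),
            "; chains may not have mixed")
  out
}

#' @export
print.chain_output <- function(x, ...) {
  cat("<chain_output>", nrow(x$draws), "retained draws x", ncol(x$draws),
      "dimensions (", length(x$per_chain), "chains )\n")
  cat("  acceptance:", paste(round(range(x$acceptance_rate), 3), collapse = "-"),
      "| max R-hat:", format(suppressWarnings(max(x$rhat, na.rm = TRUE)),
                             digits = 4),
      "| min ESS:", format(suppressWarnings(min(x$ess, na.rm = TRUE)),
                           digits = 4), "\n")
  invisible(x)
}

#' Sample the conditional latent distribution at fixed parameters
#'
#' Per-observation independent random-walk Metropolis chains targeting
#' \eqn{f(x_i | y_i, w_i; \theta) \propto} the i-th joint term as a function
#' of \eqn{x_i}. All observations are updated in one vectorised sweep per
#' iteration. Proposal scales start at 2.4 times the Laplace conditional SD,
#' adapt during burn-in towards acceptance in [0.3, 0.5], and are then
#' frozen. Chains start dispersed around the latent mode.
#'
#' @inheritParams inner_modes
#' @param cfg a [chain_config()].
#' @return a `chain_output`; `draws` is (retained draws) x n.
#' @export
sample_conditional_latent <- function(spec, theta, data, cfg = chain_config()) {
  theta <- check_theta(spec, theta)
  im <- inner_modes(spec, theta, data, inner_config("multistart"))
  sd0 <- 1 / sqrt(-im$curvatures)
  n <- data$n
  kept <- floor((cfg$iterations - cfg$burn_in) / cfg$thin)
  offsets <- c(0, 2, -2, 4, -4)
  per_chain <- vector("list", cfg$n_chains)
  acc_all <- matrix(0, cfg$n_chains, n)
  s_final <- NULL
  for (c in seq_len(cfg$n_chains)) {
    set.seed(child_seed(cfg$seed, c))
    x <- im$modes + offsets[1 + (c - 1) %% length(offsets)] * sd0
    f <- log_terms(spec, theta, x, data)
    bad <- !is.finite(f)
    if (any(bad)) { x[bad] <- im$modes[bad]; f <- log_terms(spec, theta, x, data) }
    s <- if (identical(cfg$proposal_sd, "adaptive")) 2.4 * sd0
         else rep(cfg$proposal_sd, n)
    draws <- matrix(NA_real_, kept, n)
    acc_window <- acc_post <- numeric(n)
    k <- 0
    for (t in seq_len(cfg$iterations)) {
      xp <- x + s * stats::rnorm(n)
      fp <- log_terms(spec, theta, xp, data)
      a <- log(stats::runif(n)) < (fp - f)
      a[!is.finite(fp)] <- FALSE
      x[a] <- xp[a]; f[a] <- fp[a]
      if (t <= cfg$burn_in) {
        acc_window <- acc_window + a
        if (identical(cfg$proposal_sd, "adaptive") && t %% 50 == 0) {
          s <- s * exp(0.8 * (acc_window / 50 - 0.4))
          acc_window[] <- 0
        }
      } else {
        acc_post <- acc_post + a
        if ((t - cfg$burn_in) %% cfg$thin == 0) {
          k <- k + 1
          draws[k, ] <- x
        }
      }
    }
    per_chain[[c]] <- draws[seq_len(k), , drop = FALSE]
    acc_all[c, ] <- acc_post / (cfg$iterations - cfg$burn_in)
    s_final <- s
  }
  new_chain_output(per_chain, colMeans(acc_all), s_final)
}

#' Sample the data-cloning posterior over the parameters
#'
#' Metropolis-within-Gibbs targeting
#' \eqn{\pi_K(\theta, x^{(1)}, \dots, x^{(K)} | y) \propto
#' \prod_k f(y, x^{(k)}; \theta)\, \pi(\theta)}: the posterior obtained from
#' K conceptual copies of the data. Latents are updated in one vectorised
#' element-wise sweep (they are conditionally independent); each free
#' parameter then gets a scalar random-walk update on its unconstrained
#' (log for dispersions) scale. The prior is Gaussian on the unconstrained
#' scale. Returns natural-scale parameter draws.
#'
#' @inheritParams inner_modes
#' @param K number of clones (>= 1).
#' @param prior list with `mean` and `sd` (scalars or named vectors over the
#'   free parameters) of the Gaussian prior on the unconstrained scale.
#' @param cfg a [chain_config()].
#' @param theta_init named full parameter vector: initial values for free
#'   parameters, fixed values for the rest.
#' @return a `chain_output`; `draws` is (retained draws) x (free parameters).
#' @export
sample_dc_posterior <- function(spec, data, K, prior = list(mean = 0, sd = 10),
                                cfg = chain_config(), theta_init = NULL) {
  stopifnot(K >= 1)
  if (is.null(theta_init)) stop("theta_init must be supplied")
  theta_init <- check_theta(spec, theta_init)
  free <- spec$free_parameters
  p <- length(free)
  pm <- rep_len(if (!is.null(names(prior$mean))) prior$mean[free] else prior$mean, p)
  ps <- rep_len(if (!is.null(names(prior$sd))) prior$sd[free] else prior$sd, p)
  n <- data$n
  kept <- floor((cfg$iterations - cfg$burn_in) / cfg$thin)
  per_chain <- vector("list", cfg$n_chains)
  acc_theta <- matrix(0, cfg$n_chains, p)
  for (c in seq_len(cfg$n_chains)) {
    set.seed(child_seed(cfg$seed, 100 + c))
    th_t <- to_transformed(theta_init, free) +
      (c - 1) * stats::rnorm(p, 0, 0.1)          # mildly dispersed starts
    theta <- from_transformed(th_t, free, theta_init)
    im <- inner_modes(spec, theta, data, inner_config("multistart"))
    X <- matrix(im$modes, n, K) + matrix(stats::rnorm(n * K), n, K) /
      sqrt(-im$curvatures)
    Fx <- matrix(log_terms(spec, theta, X, data), n, K)
    sx <- 2.4 / sqrt(-im$curvatures)             # latent proposal scale
    st <- rep(0.3, p)                            # componentwise theta scales
    draws <- matrix(NA_real_, kept, p)
    accw_x <- numeric(n); accw_t <- accp_t <- numeric(p)
    ## second half of burn-in switches to joint proposals with the
    ## empirical covariance of the early draws (ridge-shaped posteriors mix
    ## poorly under componentwise walks); frozen after burn-in
    hist_t <- matrix(NA_real_, cfg$burn_in, p)
    prop_chol <- NULL
    sj <- 2.38 / sqrt(p)
    accw_j <- 0; accp_j <- 0; nj <- 0
    k <- 0
    for (t in seq_len(cfg$iterations)) {
      ## latent sweep
      Xp <- X + sx * matrix(stats::rnorm(n * K), n, K)
      Fp <- matrix(log_terms(spec, theta, Xp, data), n, K)
      A <- matrix(log(stats::runif(n * K)), n, K) < (Fp - Fx)
      A[!is.finite(Fp)] <- FALSE
      X[A] <- Xp[A]; Fx[A] <- Fp[A]
      ## theta update: componentwise walks, or a joint adaptive proposal
      if (is.null(prop_chol)) {
        for (j in seq_len(p)) {
          th_p <- th_t
          th_p[j] <- th_p[j] + st[j] * stats::rnorm(1)
          theta_p <- from_transformed(th_p, free, theta_init)
          Fpm <- matrix(log_terms(spec, theta_p, X, data), n, K)
          lp <- sum(Fpm) + sum(stats::dnorm(th_p, pm, ps, log = TRUE))
          lcur <- sum(Fx) + sum(stats::dnorm(th_t, pm, ps, log = TRUE))
          if (is.finite(lp) && log(stats::runif(1)) < lp - lcur) {
            th_t <- th_p; theta <- theta_p; Fx <- Fpm
            if (t <= cfg$burn_in) accw_t[j] <- accw_t[j] + 1
            else accp_t[j] <- accp_t[j] + 1
          }
        }
      } else {
        nj <- nj + 1
        th_p <- th_t + sj * drop(stats::rnorm(p) %*% prop_chol)
        theta_p <- from_transformed(th_p, free, theta_init)
        Fpm <- matrix(log_terms(spec, theta_p, X, data), n, K)
        lp <- sum(Fpm) + sum(stats::dnorm(th_p, pm, ps, log = TRUE))
        lcur <- sum(Fx) + sum(stats::dnorm(th_t, pm, ps, log = TRUE))
        if (is.finite(lp) && log(stats::runif(1)) < lp - lcur) {
          th_t <- th_p; theta <- theta_p; Fx <- Fpm
          if (t <= cfg$burn_in) accw_j <- accw_j + 1 else accp_j <- accp_j + 1
        }
      }
      if (t <= cfg$burn_in) {
        hist_t[t, ] <- th_t
        accw_x <- accw_x + rowMeans(A)
        if (t %% 50 == 0) {
          sx <- sx * exp(0.8 * (accw_x / 50 - 0.4))
          st <- st * exp(0.8 * (accw_t / 50 - 0.35))
          accw_x[] <- 0; accw_t[] <- 0
          if (!is.null(prop_chol)) {
            sj <- sj * exp(0.8 * (accw_j / 50 - 0.3))
            accw_j <- 0
          }
        }
        if (p > 1 && t == max(200, floor(cfg$burn_in / 2))) {
          S <- stats::cov(hist_t[seq_len(t), , drop = FALSE]) +
            diag(1e-8, p)
          ch_S <- try(chol(S), silent = TRUE)
          if (!inherits(ch_S, "try-error")) prop_chol <- ch_S
        }
      } else if ((t - cfg$burn_in) %% cfg$thin == 0) {
        k <- k + 1
        draws[k, ] <- from_transformed(th_t, free, theta_init)[free]
      }
    }
    per_chain[[c]] <- draws[seq_len(k), , drop = FALSE]
    acc_theta[c, ] <- if (is.null(prop_chol))
      accp_t / (cfg$iterations - cfg$burn_in)
    else rep(accp_j / (cfg$iterations - cfg$burn_in), p)
  }
  new_chain_output(per_chain, colMeans(acc_theta), NULL, param_names = free)
}
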