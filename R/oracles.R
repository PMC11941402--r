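#' Quadrature configuration for the exact marginal likelihood
#'
#' @param rule `"adaptive"` (default) evaluates each observation's latent
#'   integral with [stats::integrate()] over the whole real line, in log
#'   space via a max-shift at the latent mode; `"fixed_node"` uses a
#'   composite Gauss-Legendre rule with about `node_count` nodes per
#'   observation — a centre panel scaled to the Laplace conditional SD plus
#'   two tail panels on the measurement/latent scale (fast, fully
#'   vectorised; falls back to the adaptive rule for the quadratic-mean
#'   Poisson family, whose conditional latent density is bimodal and not
#'   safely covered by mode-centred panels).
#' @param node_count total fixed-rule node budget per observation (>= 21).
#' @param rel_tol relative tolerance of the adaptive rule.
#' @return an object of class `quad_config`.
#' @export
quad_config <- function(rule = c("adaptive", "fixed_node"), node_count = 151,
                        rel_tol = 1e-10) {
  rule <- match.arg(rule)
  stopifnot(node_count >= 21, rel_tol > 0, rel_tol <= 1e-6)
  structure(list(rule = rule, node_count = node_count, rel_tol = rel_tol),
            class = "quad_config")
}

## subset a dataset to observation indices
data_subset <- function(data, i) {
  eiv_data(data$y[i], if (!is.null(data$w)) data$w[i], family = data$family,
           true_theta = data$true_theta, seed = data$seed)
}

## per-observation marginal log-likelihoods log \int f(y_i|x) f(w_i|x) g(x) dx
obs_marginal_loglik <- function(spec, theta, data, cfg = quad_config()) {
  theta <- check_theta(spec, theta)
  if (cfg$rule == "fixed_node" && spec$family != "poisson_quadratic") {
    ## composite Gauss-Legendre panels per observation: a centre panel
    ## scaled to the Laplace conditional SD (resolving arbitrarily narrow
    ## spikes) plus two tail panels on the scale of the smooth density
    ## components (covering the polynomial tails of the heavy-tailed latent
    ## law, where a Gauss-Hermite rule converges too slowly)
    im <- inner_modes(spec, theta, data, inner_config("multistart"))
    sd_i <- 1 / sqrt(-im$curvatures)
    bg <- max(1e-3,
              if (spec$has_covariate_observation) unname(theta["sigma1"]),
              switch(spec$family,
                     variance_partition = sqrt(unname(theta["tau2"])),
                     if (spec$latent == "normal") spec$latent_sd else 1))
    B <- pmax(sd_i, bg)
    s <- pmin(sd_i, B)
    k_tail <- max(8L, as.integer(cfg$node_count %/% 6))
    k_cen <- max(8L, as.integer(ceiling((cfg$node_count - 2 * k_tail) / 4)))
    gc_ <- gauss_legendre_cached(k_cen)
    gt_ <- gauss_legendre_cached(k_tail)
    ## centre region split at mode and +-2.5 SD (Legendre nodes cluster at
    ## panel edges, so the splits concentrate resolution around the mode and
    ## the flanks where skewed integrands put their structure)
    lo <- pmax(im$modes - 13 * B, im$modes - 8 * s)
    hi <- pmin(im$modes + 13 * B, im$modes + 8 * s)
    edges <- cbind(im$modes - 13 * B, lo,
                   pmax(lo, im$modes - 2.5 * s), im$modes,
                   pmin(hi, im$modes + 2.5 * s), hi,
                   im$modes + 13 * B)
    panel <- function(a, b, gq) {
      h <- (b - a) / 2
      X <- a + h %o% (gq$nodes + 1)
      L <- matrix(log_terms(spec, theta, X, data), nrow = data$n)
      L <- sweep(L, 2, log(gq$weights), "+") + log(pmax(h, 1e-300))
      L[h <= 0, ] <- -Inf
      L
    }
    L <- cbind(panel(edges[, 1], edges[, 2], gt_),
               panel(edges[, 2], edges[, 3], gc_),
               panel(edges[, 3], edges[, 4], gc_),
               panel(edges[, 4], edges[, 5], gc_),
               panel(edges[, 5], edges[, 6], gc_),
               panel(edges[, 6], edges[, 7], gt_))
    m <- L[cbind(seq_len(data$n), max.col(L, ties.method = "first"))]
    return(m + log(rowSums(exp(L - m))))
  }
  vapply(seq_len(data$n), function(i)
    adaptive_obs_loglik(spec, theta, data_subset(data, i), i, cfg$rel_tol), 0)
}

## memoised quadrature rules (gauss.quad solves an eigenproblem per call)
gh_cache <- new.env(parent = emptyenv())
gauss_legendre_cached <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]]))
    gh_cache[[key]] <- statmod::gauss.quad(n, kind = "legendre")
  gh_cache[[key]]
}

## fixed 401-node Gauss-Legendre panel integral (noise-robust fallback)
gl_panel <- local({
  gq <- NULL
  function(g, a, b) {
    if (is.null(gq)) gq <<- statmod::gauss.quad(401, kind = "legendre")
    h <- (b - a) / 2
    sum(gq$weights * g(a + h * (gq$nodes + 1))) * h
  }
})

## latent-mode candidates for one observation: every local maximum of the
## integrand is a stationary point of the joint term, and each multiplicative
## component (measurement, response, latent law) can pull a mode towards its
## own centre, so Newton is started from all component-informed points
obs_mode_candidates <- function(spec, theta, di) {
  beta <- unname(if (spec$family %in% eiv_families()) theta["beta"] else 0)
  resp <- switch(spec$family,
    normal_eiv = if (abs(beta) > 1e-12) di$y / beta,
    poisson_eiv = if (abs(beta) > 1e-12) log(max(di$y, 0.5)) / beta,
    poisson_quadratic = c(1, -1) * sqrt(di$y + 0.25),
    variance_partition = di$y,
    NULL)
  latent_centre <- switch(spec$family,
    poisson_quadratic = unname(theta["beta"]),
    variance_partition = unname(theta["mu"]),
    0)
  starts <- unique(c(di$w, if (!is.null(di$w)) -di$w, resp, latent_centre))
  starts <- starts[is.finite(starts)]
  modes <- sds <- objs <- numeric(0)
  for (s in starts) {
    r <- newton_ascent(spec, theta, di, s, 1e-10, 200)
    if (!is.finite(r$f) || !is.finite(r$h) || r$h >= 0) next
    if (length(modes) && any(abs(modes - r$x) < 1e-6 * (1 + abs(r$x)))) next
    modes <- c(modes, r$x); sds <- c(sds, 1 / sqrt(-r$h)); objs <- c(objs, r$f)
  }
  if (!length(modes)) stop("no latent mode found")
  list(modes = modes, sds = sds, objs = objs,
       background_scale = max(1e-3,
         if (spec$has_covariate_observation) unname(theta["sigma1"]),
         switch(spec$family,
                poisson_quadratic = sqrt(spec$quad_latent_var),
                variance_partition = sqrt(unname(theta["tau2"])),
                if (spec$latent == "normal") spec$latent_sd else 1)),
       centres = c(starts, latent_centre))
}

## one observation's marginal log-likelihood by panel-decomposed adaptive
## quadrature: a scaled panel around each detected latent mode (so arbitrarily
## narrow spikes are resolved exactly) plus background panels on the scale of
## the smooth density components; outside the union the integrand is bounded
## by component tails at under exp(-70) of the peak
adaptive_obs_loglik <- function(spec, theta, di, i, rel_tol) {
  mc <- obs_mode_candidates(spec, theta, di)
  shift <- max(mc$objs)
  f <- function(x) {
    dx <- list(y = rep(di$y, length(x)),
               w = if (!is.null(di$w)) rep(di$w, length(x)), n = length(x))
    v <- exp(log_terms(spec, theta, x, dx) - shift)
    v[!is.finite(v)] <- 0
    v
  }
  bg <- mc$background_scale
  halfw <- pmin(40 * mc$sds, 200 * bg)
  lo <- c(mc$modes - halfw, mc$centres - 13 * bg)
  hi <- c(mc$modes + halfw, mc$centres + 13 * bg)
  ## merge overlapping windows into disjoint panels, then cut each panel at
  ## interior mode-window edges so narrow spikes sit in their own sub-panel
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  panels <- list(c(lo[1], hi[1]))
  for (k in seq_along(lo)[-1]) {
    last <- panels[[length(panels)]]
    if (lo[k] <= last[2]) panels[[length(panels)]] <- c(last[1], max(last[2], hi[k]))
    else panels[[length(panels) + 1]] <- c(lo[k], hi[k])
  }
  cuts <- sort(unique(c(mc$modes - halfw, mc$modes + halfw)))
  total <- 0
  for (p in panels) {
    edges <- sort(unique(c(p, cuts[cuts > p[1] & cuts < p[2]])))
    for (s in seq_len(length(edges) - 1)) {
      a <- edges[s]; b <- edges[s + 1]
      ## integrate in a scaled variable centred on the segment's own feature:
      ## the narrowest mode inside it, or the background scale
      inside <- which(mc$modes >= a - 1e-12 & mc$modes <= b + 1e-12)
      sc <- if (length(inside)) min(mc$sds[inside], bg) else bg
      ctr <- if (length(inside)) mc$modes[inside[which.min(mc$sds[inside])]]
             else (a + b) / 2
      g <- function(u) f(ctr + sc * u) * sc
      val <- try(stats::integrate(g, (a - ctr) / sc, (b - ctr) / sc,
                                  rel.tol = rel_tol, abs.tol = 1e-14,
                                  subdivisions = 400L)$value, silent = TRUE)
      if (inherits(val, "try-error"))
        val <- try(stats::integrate(g, (a - ctr) / sc, (b - ctr) / sc,
                                    rel.tol = rel_tol * 1e3, abs.tol = 1e-12,
                                    subdivisions = 800L)$value, silent = TRUE)
      if (inherits(val, "try-error"))
        ## extreme observations make the log joint O(1e14), whose double-
        ## precision noise defeats adaptive refinement; a fixed high-order
        ## rule averages that noise instead of chasing it
        val <- gl_panel(g, (a - ctr) / sc, (b - ctr) / sc)
      if (!is.finite(val))
        stop("quadrature failed to converge for observation ", i)
      total <- total + val
    }
  }
  if (total <= 0) stop("quadrature failed to converge for observation ", i)
  log(total) + shift
}

#' Exact marginal log-likelihood by one-dimensional quadrature
#'
#' The deterministic gold standard: each observation contributes
#' \eqn{\log \int f(y_i|x;\theta) f(w_i|x;\theta) g(x;\theta)\,dx}, evaluated
#' by adaptive quadrature in log space (max-shifted at the latent mode to
#' avoid underflow).
#'
#' @inheritParams inner_modes
#' @param cfg a [quad_config()].
#' @return scalar log-likelihood.
#' @export
quadrature_loglik <- function(spec, theta, data, cfg = quad_config()) {
  sum(obs_marginal_loglik(spec, theta, data, cfg))
}

## standardised latent draws for the simple Monte Carlo likelihood (common
## random numbers: the same seed always yields the same draws)
mc_latent_draws <- function(spec, M, seed) {
  set.seed(seed)
  switch(spec$family,
    poisson_quadratic = ,
    variance_partition = stats::rnorm(M),
    if (spec$latent == "t") stats::rt(M, spec$latent_df)
    else stats::rnorm(M))
}

## fast slope-only Monte Carlo log-likelihood for the EIV families: one
## factory call per dataset precomputes everything that does not depend on
## the slope, so each curve evaluation is a few fused element-wise passes
mc_beta_loglik_factory <- function(spec, data, theta_base, M = 20000,
                                   seed = 1) {
  stopifnot(spec$family %in% eiv_families())
  theta_base <- check_theta(spec, theta_base)
  x <- mc_latent_draws(spec, M, seed)
  if (spec$latent == "normal") x <- spec$latent_sd * x
  n <- data$n
  X <- matrix(x, n, M, byrow = TRUE)
  LW <- stats::dnorm(data$w, X, theta_base["sigma1"], log = TRUE)
  y <- data$y
  pre <- switch(spec$family,
    normal_eiv = list(YX = outer(y, x), X2 = X^2, Y2 = y^2,
                      s2sq = unname(theta_base["sigma2"])^2),
    poisson_eiv = list(YX = outer(y, x), LG = lgamma(y + 1)),
    list(Y = matrix(y, n, M)))
  function(beta) {
    LY <- switch(spec$family,
      normal_eiv = -0.5 * log(2 * pi * pre$s2sq) -
        (pre$Y2 - 2 * beta * pre$YX + beta^2 * pre$X2) / (2 * pre$s2sq),
      poisson_eiv = beta * pre$YX - exp(beta * X) - pre$LG,
      logit_eiv = {
        eta <- beta * X
        pre$Y * stats::plogis(eta, log.p = TRUE) +
          (1 - pre$Y) * stats::plogis(-eta, log.p = TRUE)
      },
      probit_eiv = {
        eta <- beta * X
        pre$Y * stats::pnorm(eta, log.p = TRUE) +
          (1 - pre$Y) * stats::pnorm(-eta, log.p = TRUE)
      })
    L <- LY + LW
    m <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
    bad <- !is.finite(m)
    W <- exp(L - ifelse(is.finite(m), m, 0))
    mu_i <- rowSums(W) / M
    sd_i <- sqrt(pmax(rowSums(W^2) - M * mu_i^2, 0) / (M - 1))
    se_i <- sd_i / (sqrt(M) * mu_i)
    list(value = sum(ifelse(bad, -Inf, m + log(mu_i))),
         se = sqrt(sum(se_i[!bad]^2)))
  }
}

#' Simple Monte Carlo marginal log-likelihood
#'
#' Per observation, \eqn{\hat L_i = M^{-1}\sum_j f(y_i|x_j) f(w_i|x_j)} with
#' \eqn{x_j} drawn i.i.d. from the latent law \eqn{g(x;\theta)}; returns
#' \eqn{\sum_i \log \hat L_i} and a delta-method standard error. The same
#' seed reuses the same underlying uniform/normal draws across calls, so
#' curves evaluated over a parameter grid with a fixed seed use common random
#' numbers and are smooth in the parameter.
#'
#' @inheritParams inner_modes
#' @param M number of Monte Carlo draws per observation (>= 100).
#' @param seed integer seed.
#' @return a list with `value` (log-likelihood) and `se`.
#' @export
mc_loglik <- function(spec, theta, data, M = 20000, seed = 1) {
  theta <- check_theta(spec, theta)
  stopifnot(M >= 100)
  ## latent draws written mean + scale * standardised draw so that common
  ## random numbers carry across theta
  z <- mc_latent_draws(spec, M, seed)
  x <- switch(spec$family,
    poisson_quadratic = theta["beta"] + sqrt(spec$quad_latent_var) * z,
    variance_partition = theta["mu"] + sqrt(theta["tau2"]) * z,
    if (spec$latent == "t") z else spec$latent_sd * z)
  X <- matrix(x, nrow = data$n, ncol = M, byrow = TRUE)
  L <- matrix(data_loglik_terms(spec, theta, X, data), nrow = data$n)
  m <- L[cbind(seq_len(data$n), max.col(L, ties.method = "first"))]
  bad <- !is.finite(m)
  if (any(bad))
    warning("all Monte Carlo weights are zero for observation(s) ",
            paste(which(bad), collapse = ", "))
  W <- exp(L - ifelse(is.finite(m), m, 0))
  mu_i <- rowSums(W) / M
  sd_i <- sqrt(pmax(rowSums(W^2) - M * mu_i^2, 0) / (M - 1))
  se_i <- sd_i / (sqrt(M) * mu_i)
  value <- sum(ifelse(bad, -Inf, m + log(mu_i)))
  list(value = value, se = sqrt(sum(se_i[!bad]^2)))
}

## ---- likelihood curves ---------------------------------------------------

new_likelihood_curve <- function(parameter, grid, loglik_by_method,
                                 se = NULL, extra = NULL) {
  if (is.unsorted(grid, strictly = TRUE)) {
    o <- order(grid)
    grid <- grid[o]
    loglik_by_method <- lapply(loglik_by_method, `[`, o)
    if (!is.null(se)) se <- lapply(se, `[`, o)
  }
  rel <- lapply(loglik_by_method, function(l) {
    m <- suppressWarnings(max(l, na.rm = TRUE))
    exp(l - m)
  })
  structure(c(list(parameter = parameter, grid = grid,
                   loglik = loglik_by_method, relative = rel, se = se),
              extra),
            class = "likelihood_curve")
}

#' @export
print.likelihood_curve <- function(x, ...) {
  cat("<likelihood_curve> parameter:", x$parameter, "|", length(x$grid),
      "grid points in [", format(min(x$grid)), ",", format(max(x$grid)), "]\n")
  for (m in names(x$loglik)) {
    am <- x$grid[which.max(x$loglik[[m]])]
    cat(sprintf("  %-10s argmax = %8.4f  max logL = %s\n", m, am,
                format(suppressWarnings(max(x$loglik[[m]], na.rm = TRUE)),
                       digits = 7)))
  }
  invisible(x)
}

#' @export
as.data.frame.likelihood_curve <- function(x, ...) {
  do.call(rbind, lapply(names(x$loglik), function(m)
    data.frame(parameter = x$parameter, value = x$grid, method = m,
               loglik = x$loglik[[m]], relative = x$relative[[m]])))
}

#' @export
plot.likelihood_curve <- function(x, ...) {
  R <- do.call(cbind, x$relative)
  graphics::matplot(x$grid, R, type = "l", lty = 1, lwd = 2,
                    xlab = x$parameter, ylab = "relative likelihood", ...)
  graphics::legend("topright", legend = colnames(R), lty = 1, lwd = 2,
                   col = seq_len(ncol(R)), bty = "n")
  invisible(x)
}

#' Relative-likelihood curves for one parameter under several methods
#'
#' Evaluates each requested method on a parameter grid, holding the other
#' parameters fixed at `theta`, and normalises each curve by its own maximum
#' so curves are comparable on the (0, 1] relative-likelihood scale.
#'
#' @inheritParams inner_modes
#' @param parameter name of the varying parameter.
#' @param grid strictly increasing grid of parameter values.
#' @param methods subset of `"quadrature"`, `"mc"`, `"laml"`, `"gt"`.
#' @param quad_cfg,inner_cfg,chain_cfg method configurations.
#' @param mc_M,mc_seed Monte Carlo sample size and seed.
#' @param gt_reference reference theta for the Geyer-Thompson curve; default
#'   is the grid maximiser of the first exact method available (anchoring
#'   the ratio estimator at the MLE is where it behaves best).
#' @return a `likelihood_curve`; failures at grid points become `NA`.
#' @export
likelihood_curve <- function(spec, data, parameter, grid, theta,
                             methods = c("quadrature", "mc", "laml"),
                             quad_cfg = quad_config(),
                             inner_cfg = inner_config(),
                             chain_cfg = chain_config(),
                             mc_M = 20000, mc_seed = 1,
                             gt_reference = NULL) {
  theta <- check_theta(spec, theta)
  eval_grid <- function(f) vapply(grid, function(p) {
    th <- theta; th[parameter] <- p
    out <- try(f(th), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) NA_real_ else out
  }, 0)
  ll <- list(); se <- list()
  if ("quadrature" %in% methods)
    ll$quadrature <- eval_grid(function(th) quadrature_loglik(spec, th, data, quad_cfg))
  if ("mc" %in% methods) {
    vals <- lapply(grid, function(p) {
      th <- theta; th[parameter] <- p
      out <- try(mc_loglik(spec, th, data, mc_M, mc_seed), silent = TRUE)
      if (inherits(out, "try-error")) list(value = NA_real_, se = NA_real_) else out
    })
    ll$mc <- vapply(vals, `[[`, 0, "value")
    se$mc <- vapply(vals, `[[`, 0, "se")
  }
  if ("laml" %in% methods)
    ll$laml <- eval_grid(function(th) laml_loglik(spec, th, data, inner_cfg))
  if ("gt" %in% methods) {
    ref <- gt_reference
    if (is.null(ref)) {
      anchor <- if (length(ll)) grid[which.max(ll[[1]])] else grid[ceiling(length(grid) / 2)]
      ref <- theta; ref[parameter] <- anchor
    }
    gt <- try(gt_curve(spec, data, parameter, grid, references = list(ref),
                       theta = theta, chain_cfg = chain_cfg), silent = TRUE)
    if (!inherits(gt, "try-error")) ll$gt <- gt$log_ratio  # arbitrary constant
  }
  new_likelihood_curve(parameter, grid, ll, se = if (length(se)) se)
}

#' Likelihood-ratio confidence interval for a scalar parameter
#'
#' Inverts the likelihood-ratio test: returns the connected set
#' \eqn{\{\theta : 2(\ell(\hat\theta) - \ell(\theta)) \le \chi^2_1(level)\}}
#' around the maximiser, endpoints located by root bisection. The maximiser
#' is found by a coarse grid scan plus golden-section refinement so a
#' secondary mode inside the search range does not trap the estimate.
#'
#' @param loglik function of one numeric argument returning a log-likelihood.
#' @param range numeric length-2 search range.
#' @param level confidence level in (0, 1].
#' @param n_grid coarse-scan size.
#' @return numeric `c(lower, upper)` with attributes `estimate`, `maximum`,
#'   `open_lower`/`open_upper` (`TRUE` when the interval is clipped by the
#'   search range).
#' @export
lr_confidence_interval <- function(loglik, range, level = 0.95, n_grid = 41) {
  stopifnot(level > 0, level <= 1)
  fit <- fit_scalar_param(loglik, range, n_grid)
  if (level == 1) {
    out <- range
    attr(out, "open_lower") <- attr(out, "open_upper") <- TRUE
    attr(out, "estimate") <- fit$par; attr(out, "maximum") <- fit$value
    return(out)
  }
  cut <- stats::qchisq(level, df = 1) / 2
  g <- function(p) {
    v <- try(loglik(p), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) v <- -Inf
    (fit$value - v) - cut
  }
  side <- function(a, b) {  # root of g between a (inside) and b (outside)
    gb <- g(b)
    if (gb < 0) return(structure(b, open = TRUE))
    structure(stats::uniroot(g, c(min(a, b), max(a, b)), tol = 1e-4)$root,
              open = FALSE)
  }
  lo <- side(fit$par, range[1])
  hi <- side(fit$par, range[2])
  out <- c(as.numeric(lo), as.numeric(hi))
  attr(out, "estimate") <- fit$par
  attr(out, "maximum") <- fit$value
  attr(out, "open_lower") <- attr(lo, "open")
  attr(out, "open_upper") <- attr(hi, "open")
  out
}

#' Profile likelihood from the exact (quadrature) marginal likelihood
#'
#' For each value of the interest parameter, maximises the quadrature
#' log-likelihood over the remaining free parameters, warm-starting from the
#' neighbouring grid point. This is the package's gold-standard profile for
#' multiparameter comparisons.
#'
#' @inheritParams profile_laml
#' @param cfg a [quad_config()].
#' @return a `likelihood_curve` with method `"quadrature"`.
#' @export
profile_loglik_oracle <- function(spec, data, psi_name, psi_grid, theta_base,
                                  cfg = quad_config()) {
  theta_base <- check_theta(spec, theta_base)
  res <- profile_over_nuisance(
    function(th) quadrature_loglik(spec, th, data, cfg),
    spec, theta_base, psi_name, psi_grid, spec$free_parameters)
  new_likelihood_curve(psi_name, psi_grid, list(quadrature = res$loglik),
                       extra = list(converged = res$converged,
                                    nuisance = res$nuisance))
}
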