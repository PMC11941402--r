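#' Configuration for the inner (latent) optimisation
#'
#' @param start_policy where the per-observation Newton iterations start:
#'   `"observed_w"` starts each latent at its measurement \eqn{w_i} (moment
#'   estimates for the families without a w), `"zero"` at 0, `"multistart"`
#'   runs several starts per observation and keeps the best local maximiser
#'   while recording all distinct optima found, `"custom"` uses
#'   `start_values`.
#' @param multistart_count maximum number of starts per observation under
#'   `"multistart"`.
#' @param newton_tol convergence tolerance on the latent gradient.
#' @param max_iter maximum Newton iterations.
#' @param start_values numeric vector of custom starts (policy `"custom"`).
#' @return an object of class `inner_config`.
#' @export
inner_config <- function(start_policy = c("observed_w", "zero", "multistart",
                                          "custom"),
                         multistart_count = 3, newton_tol = 1e-10,
                         max_iter = 200, start_values = NULL) {
  start_policy <- match.arg(start_policy)
  stopifnot(newton_tol > 0, newton_tol <= 1e-8, max_iter >= 1)
  structure(list(start_policy = start_policy,
                 multistart_count = multistart_count,
                 newton_tol = newton_tol, max_iter = max_iter,
                 start_values = start_values),
            class = "inner_config")
}

## starting values per policy; a list of length-n vectors (one per start)
inner_start_list <- function(spec, theta, data, cfg) {
  n <- data$n
  moment_start <- switch(spec$family,
    poisson_quadratic = sqrt(data$y + 0.25),
    variance_partition = data$y,
    data$w)
  zero_start <- switch(spec$family,
    ## x = 0 is outside the support of the quadratic-mean Poisson term when
    ## y > 0; the "zero" policy therefore nudges to a small positive value
    poisson_quadratic = rep(0.1, n),
    variance_partition = rep(0, n),
    rep(0, n))
  switch(cfg$start_policy,
    observed_w = list(moment_start),
    zero = list(zero_start),
    custom = {
      if (is.null(cfg$start_values)) stop("custom policy needs start_values")
      list(rep_len(cfg$start_values, n))
    },
    multistart = {
      s <- switch(spec$family,
        poisson_quadratic = list(sqrt(data$y + 0.25), -sqrt(data$y + 0.25),
                                 rep(0.1, n)),
        variance_partition = list(data$y, rep(mean(data$y), n), rep(0, n)),
        list(data$w, -data$w, rep(0, n)))
      s[seq_len(min(cfg$multistart_count, length(s)))]
    })
}

## vectorised safeguarded Newton ascent on the n independent 1-D problems;
## converged observations leave the active set, and the gradient criterion is
## scaled by the magnitude of the objective because extreme observations
## (counts of order 1e12 and larger under the heavy-tailed latent law) carry
## irreducible double-precision noise proportional to |log f|
newton_ascent <- function(spec, theta, data, x0, tol, max_iter) {
  n <- data$n
  x <- as.numeric(x0)
  f <- log_terms(spec, theta, x, data)
  done <- rep(FALSE, n)
  ok <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    idx <- which(!done)
    if (!length(idx)) break
    sub <- list(y = data$y[idx], w = if (!is.null(data$w)) data$w[idx],
                n = length(idx))
    xs <- x[idx]; fs <- f[idx]
    g <- d1_terms(spec, theta, xs, sub)
    h <- d2_terms(spec, theta, xs, sub)
    scale <- 1 + abs(fs)
    scale[!is.finite(scale)] <- 1
    hit <- !is.na(g) & abs(g) < tol * scale
    if (any(hit)) {
      j <- idx[hit]
      done[j] <- ok[j] <- TRUE
      if (all(hit)) next
    }
    keep <- !hit
    idx <- idx[keep]; xs <- xs[keep]; fs <- fs[keep]
    g <- g[keep]; h <- h[keep]
    sub <- list(y = sub$y[keep], w = sub$w[keep], n = length(idx))
    newt <- is.finite(g) & is.finite(h) & h < 0
    step <- numeric(length(idx))
    step[newt] <- -g[newt] / h[newt]
    step[!newt] <- sign(g[!newt])
    step <- pmax(pmin(step, 25), -25)
    lam <- rep(1, length(idx))
    moved <- rep(FALSE, length(idx))
    x1 <- xs; f1 <- fs
    for (bt in 1:40) {
      trial <- which(!moved)
      if (!length(trial)) break
      xt <- xs[trial] + lam[trial] * step[trial]
      ft <- log_terms(spec, theta, xt,
                      list(y = sub$y[trial],
                           w = if (!is.null(sub$w)) sub$w[trial],
                           n = length(trial)))
      good <- is.finite(ft) & ft >= fs[trial] - 1e-12 * (1 + abs(fs[trial]))
      x1[trial[good]] <- xt[good]
      f1[trial[good]] <- ft[good]
      moved[trial[good]] <- TRUE
      lam[trial[!good]] <- lam[trial[!good]] / 2
    }
    stalled <- !moved | abs(x1 - xs) < 1e-13 * (1 + abs(xs))
    done[idx[stalled]] <- TRUE
    ok[idx[stalled]] <- ok[idx[stalled]] | moved[stalled]
    x[idx] <- x1
    f[idx] <- f1
  }
  g <- d1_terms(spec, theta, x, data)
  h <- d2_terms(spec, theta, x, data)
  list(x = x, f = f, g = g, h = h,
       converged = ok | abs(g) < sqrt(tol) * 10 * (1 + abs(f)))
}

#' Per-observation latent modes and curvatures
#'
#' Step 1 of the Laplace construction: maximise each observation's joint
#' log-density term over its latent value by safeguarded Newton ascent, and
#' return the maximiser \eqn{\hat u_i} together with the second derivative
#' (curvature) there. Under `start_policy = "multistart"` the best local
#' maximiser per observation is kept and the number of distinct local optima
#' found is recorded (`n_modes`), which is the practical red flag for a
#' multimodal conditional latent distribution.
#'
#' @inheritParams log_joint
#' @param cfg an [inner_config()].
#' @return a list with `modes`, `curvatures` (all negative at a reported
#'   optimum), `objective` (per-observation term value at the mode),
#'   `converged`, `n_modes`, `all_modes` (matrix, multistart only).
#' @export
inner_modes <- function(spec, theta, data, cfg = inner_config()) {
  theta <- check_theta(spec, theta)
  starts <- inner_start_list(spec, theta, data, cfg)
  runs <- lapply(starts, function(s)
    newton_ascent(spec, theta, data, s, cfg$newton_tol, cfg$max_iter))
  fmat <- vapply(runs, `[[`, numeric(data$n), "f")
  fmat <- matrix(fmat, nrow = data$n)
  best <- max.col(fmat, ties.method = "first")
  idx <- cbind(seq_len(data$n), best)
  xmat <- matrix(vapply(runs, `[[`, numeric(data$n), "x"), nrow = data$n)
  hmat <- matrix(vapply(runs, `[[`, numeric(data$n), "h"), nrow = data$n)
  cmat <- matrix(vapply(runs, `[[`, logical(data$n), "converged"), nrow = data$n)
  modes <- xmat[idx]; curv <- hmat[idx]; obj <- fmat[idx]
  n_modes <- apply(xmat, 1, function(r) length(unique(round(r, 4))))
  if (any(curv >= 0 & is.finite(obj)))
    stop("non-negative curvature at a reported latent optimum (observation ",
         which(curv >= 0)[1], ")")
  list(modes = modes, curvatures = curv, objective = obj,
       converged = cmat[idx], n_modes = n_modes,
       all_modes = if (length(runs) > 1) xmat)
}

#' Laplace approximation to the marginal log-likelihood
#'
#' Computes \eqn{\log f(y, \hat u; \theta) + (n/2)\log 2\pi -
#' \tfrac12 \sum_i \log(-H_i(\hat u_i))}. The \eqn{(2\pi)^{n/2}} constant is
#' included so the approximation is exact (not merely proportional) when the
#' conditional latent distribution is Gaussian; it cancels in relative
#' likelihoods.
#'
#' @inheritParams inner_modes
#' @param x_start optional length-n vector of inner starting values,
#'   overriding the policy in `cfg`; used by fitters to warm-start the inner
#'   optimisation from the previous outer iterate's latent modes (the
#'   continuation scheme nested optimisers use). The latent modes and
#'   curvatures actually used are attached as attributes `"modes"` and
#'   `"curvatures"`.
#' @return scalar approximate log-likelihood.
#' @export
laml_loglik <- function(spec, theta, data, cfg = inner_config(),
                        x_start = NULL) {
  if (!is.null(x_start)) {
    r <- newton_ascent(spec, theta, data, x_start, cfg$newton_tol,
                       cfg$max_iter)
    if (all(is.finite(r$h)) && all(r$h < 0)) {
      im <- list(modes = r$x, curvatures = r$h, objective = r$f)
    } else im <- inner_modes(spec, theta, data, cfg)
  } else im <- inner_modes(spec, theta, data, cfg)
  out <- sum(im$objective) + 0.5 * data$n * log(2 * pi) -
    0.5 * sum(log(-im$curvatures))
  attr(out, "modes") <- im$modes
  attr(out, "curvatures") <- im$curvatures
  out
}

## objective closure over theta with inner warm-start continuation; each
## fresh closure starts from the cfg policy, then tracks its own latent modes
laml_objective <- function(spec, data, cfg = inner_config()) {
  xw <- NULL
  function(theta) {
    v <- laml_loglik(spec, theta, data, cfg, x_start = xw)
    if (is.finite(v)) xw <<- attr(v, "modes")
    as.numeric(v)
  }
}

## profile over the free parameters of a generic scalar objective
## objective(theta) -> loglik; used by both the Laplace and oracle profiles
profile_over_nuisance <- function(objective, spec, theta_base, psi_name,
                                  psi_grid, free) {
  nuis <- setdiff(free, psi_name)
  ll <- rep(NA_real_, length(psi_grid))
  conv <- rep(FALSE, length(psi_grid))
  nuis_hat <- matrix(NA_real_, length(psi_grid), length(nuis),
                     dimnames = list(NULL, nuis))
  theta <- theta_base
  ## sweep outward from the grid point nearest the supplied parameter values,
  ## warm-starting each inner maximisation from its neighbour
  j0 <- which.min(abs(psi_grid - theta_base[psi_name]))
  ord <- c(j0:length(psi_grid), if (j0 > 1) (j0 - 1):1)
  start_t <- to_transformed(theta_base, nuis)
  warm <- start_t
  method <- if (length(nuis) == 1) "BFGS" else "Nelder-Mead"
  for (j in ord) {
    if (j == j0 - 1) warm <- start_t  # restart the leftward sweep
    theta[psi_name] <- psi_grid[j]
    if (length(nuis) == 0) {
      v <- try(objective(theta), silent = TRUE)
      if (!inherits(v, "try-error")) { ll[j] <- v; conv[j] <- TRUE }
      next
    }
    obj_t <- function(v) {
      th <- from_transformed(v, nuis, theta)
      out <- try(objective(th), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out)) 1e10 else -out
    }
    ctrl <- if (method == "BFGS") list(maxit = 200, reltol = 1e-10)
            else list(maxit = 500, reltol = 1e-10)
    fit <- try(stats::optim(warm, obj_t, method = method, control = ctrl),
               silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit$value) && fit$value < 1e9) {
      ll[j] <- -fit$value
      conv[j] <- fit$convergence == 0
      nuis_hat[j, ] <- from_transformed(fit$par, nuis, theta)[nuis]
      warm <- fit$par
    } else warm <- start_t
  }
  list(loglik = ll, converged = conv, nuisance = nuis_hat)
}

## 1-D fit of a single free parameter by coarse grid scan + golden refinement;
## deliberately global-ish because several of the objectives here are bimodal
fit_scalar_param <- function(objective, range = c(-6, 6), n_grid = 41) {
  grid <- seq(range[1], range[2], length.out = n_grid)
  v <- vapply(grid, function(p) {
    out <- try(objective(p), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) -Inf else out
  }, 0)
  i <- which.max(v)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  op <- stats::optimize(function(p) {
    out <- try(objective(p), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) return(1e10)
    -out
  }, c(lo, hi), tol = 1e-7)
  list(par = op$minimum, value = -op$objective, grid = grid, grid_value = v)
}

## central second difference of a scalar function (Wald curvature)
fd_second_deriv <- function(f, x, h = 1e-4 * max(1, abs(x))) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

#' Maximum likelihood under the Laplace-approximated likelihood
#'
#' Maximises [laml_loglik()] over the spec's free parameters. A single free
#' parameter is fitted by a global grid scan plus golden-section refinement
#' (the Laplace objective can be multimodal); several free parameters are
#' fitted by Nelder-Mead on log-transformed dispersions from three jittered
#' restarts, keeping the best. Wald standard errors come from the negative
#' inverse of a numerical Hessian of the approximate log-likelihood at the
#' optimum (delta method back to the natural scale).
#'
#' @inheritParams inner_modes
#' @param start named parameter vector: starting values for free parameters
#'   and fixed values for the rest.
#' @param beta_range search range used when the only free parameter is
#'   unbounded (grid-scan phase).
#' @return an object of class `laml_fit`: `theta_hat`, `latent_modes`,
#'   `inner_curvatures`, `loglik`, `wald_se`, `converged`, `start_policy`.
#' @export
laml_mle <- function(spec, data, start, cfg = inner_config(),
                     beta_range = c(-6, 6)) {
  start <- check_theta(spec, start)
  free <- spec$free_parameters
  theta <- start
  if (length(free) == 1 && !(free %in% positive_params)) {
    obj <- function(p) { th <- theta; th[free] <- p
      laml_loglik(spec, th, data, cfg) }
    fit <- fit_scalar_param(obj, beta_range)
    theta[free] <- fit$par
    ll <- fit$value
    h2 <- fd_second_deriv(obj, fit$par)
    se <- if (is.finite(h2) && h2 < 0) stats::setNames(1 / sqrt(-h2), free)
    conv <- TRUE
  } else {
    obj_t <- function(v) {
      th <- from_transformed(v, free, theta)
      out <- try(laml_loglik(spec, th, data, cfg), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out)) 1e10 else -out
    }
    t0 <- to_transformed(start, free)
    best <- NULL
    for (k in 0:2) {
      v0 <- t0 + if (k == 0) 0 else stats::rnorm(length(t0), 0, 0.3 * k)
      f <- try(stats::optim(v0, obj_t, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
      if (!inherits(f, "try-error") && (is.null(best) || f$value < best$value))
        best <- f
    }
    if (is.null(best)) stop("outer optimisation failed from all starts")
    theta <- from_transformed(best$par, free, theta)
    ll <- -best$value
    conv <- best$convergence == 0
    H <- try(stats::optimHess(best$par, obj_t), silent = TRUE)
    se <- NULL
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)  # obj_t is the negative loglik
      if (!inherits(V, "try-error") && all(diag(V) > 0))
        se <- stats::setNames(sqrt(diag(V)) * transform_jacobian(theta, free),
                              free)
    }
  }
  im <- inner_modes(spec, theta, data, cfg)
  structure(list(theta_hat = theta, latent_modes = im$modes,
                 inner_curvatures = im$curvatures, loglik = ll,
                 wald_se = se, converged = list(inner = all(im$converged),
                                                outer = isTRUE(conv)),
                 n_inner_modes = im$n_modes,
                 start_policy = cfg$start_policy),
            class = "laml_fit")
}

#' @export
print.laml_fit <- function(x, ...) {
  cat("<laml_fit> logL* =", format(x$loglik, digits = 7), "\n  theta_hat:",
      paste(names(x$theta_hat), signif(x$theta_hat, 5), sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$wald_se))
    cat("  wald se: ", paste(names(x$wald_se), signif(x$wald_se, 4),
                             sep = "=", collapse = ", "), "\n")
  cat("  converged:", x$converged$inner && x$converged$outer,
      "| inner start:", x$start_policy, "\n")
  invisible(x)
}

#' Profile of the Laplace-approximated likelihood
#'
#' For each value of the interest parameter, maximises [laml_loglik()] over
#' the remaining free parameters (warm-started from the neighbouring grid
#' point) — the Laplace analogue of [profile_loglik_oracle()].
#'
#' @inheritParams inner_modes
#' @param psi_name name of the interest parameter.
#' @param psi_grid increasing grid of interest-parameter values.
#' @param theta_base named vector of starting/fixed parameter values.
#' @return a `likelihood_curve` with method `"laml"`.
#' @export
profile_laml <- function(spec, data, psi_name, psi_grid, theta_base,
                         cfg = inner_config()) {
  theta_base <- check_theta(spec, theta_base)
  res <- profile_over_nuisance(
    function(th) laml_loglik(spec, th, data, cfg),
    spec, theta_base, psi_name, psi_grid, spec$free_parameters)
  new_likelihood_curve(psi_name, psi_grid, list(laml = res$loglik),
                       extra = list(converged = res$converged,
                                    nuisance = res$nuisance))
}
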