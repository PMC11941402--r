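## ---- shared multiparameter fitting machinery ----------------------------
## Both the exact (quadrature) likelihood and the Laplace approximation are
## maximised the same way: Nelder-Mead (BFGS for a single free parameter) on
## the transformed scale (log for dispersions), from a small set of starts
## that always includes the sign-flipped slope, because several of these
## likelihood surfaces have a genuine second mode at the mirrored slope.

## maximise obj_factory()'s objective over spec's free parameters
## obj_factory: function() -> function(theta_full) -> loglik (fresh warm state)
fit_free_params <- function(obj_factory, spec, start, starts = NULL) {
  start <- check_theta(spec, start)
  free <- spec$free_parameters
  if (is.null(starts)) {
    starts <- list(start)
    if ("beta" %in% free && abs(start["beta"]) > 1e-8) {
      s2 <- start; s2["beta"] <- -s2["beta"]
      starts <- c(starts, list(s2))
    }
  }
  best <- NULL
  for (s in starts) {
    obj <- obj_factory()
    neg <- function(v) {
      th <- from_transformed(v, free, start)
      out <- try(obj(th), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out)) 1e10 else -out
    }
    v0 <- to_transformed(check_theta(spec, s), free)
    fit <- try(if (length(free) == 1)
      stats::optim(v0, neg, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-10))
    else
      stats::optim(v0, neg, method = "Nelder-Mead",
                   control = list(maxit = 1500, reltol = 1e-9)),
      silent = TRUE)
    if (inherits(fit, "try-error") || fit$value >= 1e9) next
    if (is.null(best) || fit$value < best$fit$value)
      best <- list(fit = fit, obj = obj)
  }
  if (is.null(best)) stop("optimisation failed from all starts")
  theta_hat <- from_transformed(best$fit$par, free, start)
  neg_best <- function(v) {
    th <- from_transformed(v, free, start)
    out <- try(best$obj(th), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e10 else -out
  }
  H <- try(stats::optimHess(best$fit$par, neg_best), silent = TRUE)
  se <- NULL
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V))) &&
        all(diag(V) > 0))
      se <- stats::setNames(sqrt(diag(V)) * transform_jacobian(theta_hat, free),
                            free)
  }
  list(theta_hat = theta_hat, loglik = -best$fit$value, wald_se = se,
       converged = best$fit$convergence == 0, objective = best$obj)
}

## profile-likelihood-ratio interval for one parameter of a multiparameter
## objective: outward sweep from the MLE with warm-started nuisance
## maximisation, then secant refinement of each endpoint
profile_lr_interval <- function(obj_factory, spec, fit, param, level = 0.95,
                                step0 = NULL, range = c(-8, 8),
                                max_steps = 60) {
  free <- spec$free_parameters
  nuis <- setdiff(free, param)
  cut <- stats::qchisq(level, df = 1) / 2
  target <- fit$loglik - cut
  obj <- obj_factory()
  warm_t <- to_transformed(fit$theta_hat, nuis)
  pl <- function(p, warm) {
    th <- fit$theta_hat
    th[param] <- p
    if (!length(nuis)) {
      v <- try(obj(th), silent = TRUE)
      return(list(value = if (inherits(v, "try-error")) -Inf else v,
                  warm = warm))
    }
    neg <- function(v) {
      thv <- from_transformed(v, nuis, th)
      out <- try(obj(thv), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out)) 1e10 else -out
    }
    ## BFGS with warm start: successive profile points differ little, so a
    ## handful of quasi-Newton steps suffice (tolerance 1e-7 on the log-lik
    ## is far below the chi-square cut that defines the interval)
    f <- try(stats::optim(warm, neg, method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-7)),
             silent = TRUE)
    if (inherits(f, "try-error") || f$value >= 1e9)
      return(list(value = -Inf, warm = warm))
    list(value = -f$value, warm = f$par)
  }
  if (is.null(step0)) {
    step0 <- if (!is.null(fit$wald_se) && is.finite(fit$wald_se[param]))
      0.5 * unname(fit$wald_se[param]) else 0.2
    step0 <- min(max(step0, 0.02), 1)
  }
  one_side <- function(dir) {
    p_in <- unname(fit$theta_hat[param]); v_in <- fit$loglik
    warm <- warm_t
    open <- FALSE
    for (k in seq_len(max_steps)) {
      p_out <- p_in + dir * step0 * (if (k <= 4) 1 else 2^((k - 4) / 3))
      if (p_out < range[1] || p_out > range[2]) { open <- TRUE
        p_out <- if (dir < 0) range[1] else range[2] }
      r <- pl(p_out, warm)
      warm <- r$warm
      if (r$value < target || open) {
        if (open && r$value >= target)
          return(structure(p_out, open = TRUE))
        ## secant refinement between (p_in, v_in) and (p_out, r$value)
        a <- p_in; fa <- v_in - target
        b <- p_out; fb <- r$value - target
        for (it in 1:4) {
          m <- b - fb * (b - a) / (fb - fa)
          if (!is.finite(m) || m == b) break
          rm <- pl(m, warm)
          warm <- rm$warm
          fm <- rm$value - target
          if (!is.finite(fm)) break
          if (fm > 0) { a <- m; fa <- fm } else { b <- m; fb <- fm }
          if (abs(b - a) < 1e-4) break
        }
        return(structure((a + b) / 2, open = FALSE))
      }
      p_in <- p_out; v_in <- r$value
    }
    structure(p_in, open = TRUE)
  }
  lo <- one_side(-1); hi <- one_side(1)
  out <- c(as.numeric(lo), as.numeric(hi))
  attr(out, "estimate") <- unname(fit$theta_hat[param])
  attr(out, "open_lower") <- attr(lo, "open")
  attr(out, "open_upper") <- attr(hi, "open")
  out
}

## objective factories for the two likelihoods
quad_objective_factory <- function(spec, data, quad_cfg) {
  force(spec); force(data); force(quad_cfg)
  function() function(theta) quadrature_loglik(spec, theta, data, quad_cfg)
}

laml_objective_factory <- function(spec, data, inner_cfg) {
  force(spec); force(data); force(inner_cfg)
  function() laml_objective(spec, data, inner_cfg)
}
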