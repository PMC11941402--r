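#' Declare a hierarchical model family
#'
#' Six families are supported. Four are errors-in-variables (EIV) regressions
#' through the origin with a latent covariate \eqn{X_i} and a noisy
#' measurement \eqn{W_i | X_i \sim N(x_i, \sigma_1^2)}:
#' \describe{
#'   \item{`normal_eiv`}{\eqn{Y_i|X_i=x_i \sim N(x_i\beta, \sigma_2^2)}}
#'   \item{`poisson_eiv`}{\eqn{Y_i|X_i=x_i \sim Poisson(e^{x_i\beta})}}
#'   \item{`logit_eiv`}{\eqn{Y_i|X_i=x_i \sim Bernoulli(logit^{-1}(x_i\beta))}}
#'   \item{`probit_eiv`}{\eqn{Y_i|X_i=x_i \sim Bernoulli(\Phi(x_i\beta))}}
#' }
#' The latent covariate is a standard (unit-scale) Student t with `latent_df`
#' degrees of freedom, or, for the analytically tractable all-Gaussian
#' variant, \eqn{X_i \sim N(0, \sigma_0^2)} (`latent = "normal"`,
#' \eqn{\sigma_0} = `latent_sd`).
#'
#' Two further families are deliberately non-identifiable:
#' \describe{
#'   \item{`poisson_quadratic`}{\eqn{Y_i|X_i=x_i \sim Poisson(x_i^2)},
#'     \eqn{X_i \sim N(\beta, 5)} (the 5 is a variance); no \eqn{W}.}
#'   \item{`variance_partition`}{\eqn{Y_i|\mu_i \sim N(\mu_i, \sigma^2)},
#'     \eqn{\mu_i \sim N(\mu, \tau^2)}; only \eqn{\sigma^2+\tau^2} is
#'     identifiable. No \eqn{W}; the latent slot holds \eqn{\mu_i}.}
#' }
#'
#' @param family one of `"normal_eiv"`, `"poisson_eiv"`, `"logit_eiv"`,
#'   `"probit_eiv"`, `"poisson_quadratic"`, `"variance_partition"`.
#' @param latent_df degrees of freedom of the latent t distribution (EIV
#'   families with `latent = "t"` only).
#' @param latent latent covariate law for the EIV families: `"t"` (default)
#'   or `"normal"` (the all-Gaussian variant).
#' @param latent_sd standard deviation \eqn{\sigma_0} of the latent normal
#'   when `latent = "normal"`.
#' @param free_parameters character vector of parameters treated as free by
#'   fitters; defaults to `"beta"` for the regression families and to all
#'   three parameters for `variance_partition`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("normal_eiv", "poisson_eiv", "logit_eiv",
                                  "probit_eiv", "poisson_quadratic",
                                  "variance_partition"),
                       latent_df = 2, latent = c("t", "normal"),
                       latent_sd = 1, free_parameters = NULL) {
  family <- match.arg(family)
  latent <- match.arg(latent)
  if (!family %in% eiv_families()) latent <- "normal"
  if (latent == "t" && !(is.numeric(latent_df) && latent_df > 0))
    stop("latent_df must be a positive number")
  if (latent == "normal" && family %in% eiv_families() &&
      !(is.numeric(latent_sd) && latent_sd > 0))
    stop("latent_sd must be positive for the normal latent law")
  all_p <- family_params(family)
  if (is.null(free_parameters)) {
    free_parameters <- if (family == "variance_partition") all_p else "beta"
  }
  if (!all(free_parameters %in% all_p))
    stop("free_parameters must be a subset of {", paste(all_p, collapse = ", "),
         "} for family ", family)
  structure(
    list(family = family, latent_df = latent_df, latent = latent,
         latent_sd = latent_sd,
         has_covariate_observation = family %in% eiv_families(),
         quad_latent_var = 5,
         free_parameters = free_parameters,
         all_parameters = all_p),
    class = "model_spec")
}

eiv_families <- function() c("normal_eiv", "poisson_eiv", "logit_eiv", "probit_eiv")

family_params <- function(family) {
  switch(family,
         normal_eiv = c("beta", "sigma1", "sigma2"),
         poisson_eiv = c("beta", "sigma1"),
         logit_eiv = c("beta", "sigma1"),
         probit_eiv = c("beta", "sigma1"),
         poisson_quadratic = "beta",
         variance_partition = c("mu", "sigma2_obs", "tau2"))
}

#' @export
print.model_spec <- function(x, ...) {
  lat <- if (!x$has_covariate_observation) {
    if (x$family == "poisson_quadratic") "N(beta, 5)" else "N(mu, tau2)"
  } else if (x$latent == "t") {
    sprintf("t with %g df", x$latent_df)
  } else sprintf("N(0, %g^2)", x$latent_sd)
  cat("<model_spec> family:", x$family, "| latent:", lat,
      "| free:", paste(x$free_parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a parameter vector against a model specification
#'
#' Checks that `theta` is a fully named numeric vector containing exactly the
#' family's parameters and that scale/variance parameters are strictly
#' positive (a zero variance makes the latent law degenerate and every joint
#' density improper, so it is rejected at construction).
#'
#' @param spec a [model_spec()].
#' @param theta named numeric vector.
#' @return `theta`, invisibly, after validation.
#' @export
check_theta <- function(spec, theta) {
  p <- spec$all_parameters
  if (is.null(names(theta)) || !setequal(names(theta), p))
    stop("theta must have exactly the names {", paste(p, collapse = ", "), "}")
  theta <- theta[p]
  if (any(!is.finite(theta))) stop("theta must be finite")
  pos <- intersect(p, positive_params)
  if (length(pos) && any(theta[pos] <= 0))
    stop("parameters ", paste(pos[theta[pos] <= 0], collapse = ", "),
         " must be strictly positive")
  invisible(theta)
}

#' Construct a dataset container
#'
#' @param y response vector.
#' @param w error-prone covariate measurements, or `NULL` for families
#'   without a covariate observation.
#' @param family model family string (provenance).
#' @param true_theta generating parameters, if known.
#' @param seed generating seed, if known.
#' @return an object of class `eiv_data` with fields `y`, `w`, `n`,
#'   `family`, `true_theta`, `seed`.
#' @export
eiv_data <- function(y, w = NULL, family = NULL, true_theta = NULL, seed = NULL) {
  n <- length(y)
  if (n < 1) stop("y must be non-empty")
  if (!is.null(w) && length(w) != n) stop("length(w) must equal length(y)")
  if (!is.null(family)) {
    if (family %in% c("poisson_eiv", "poisson_quadratic") &&
        any(y < 0 | y != round(y)))
      stop("count families require nonnegative integer y")
    if (family %in% c("logit_eiv", "probit_eiv") && any(!y %in% c(0, 1)))
      stop("binary families require y in {0, 1}")
  }
  structure(list(y = as.numeric(y), w = if (!is.null(w)) as.numeric(w),
                 n = n, family = family, true_theta = true_theta, seed = seed),
            class = "eiv_data")
}

#' @export
print.eiv_data <- function(x, ...) {
  cat("<eiv_data> n =", x$n,
      if (!is.null(x$family)) paste("| family:", x$family),
      if (!is.null(x$w)) "| y, w observed" else "| y observed", "\n")
  if (!is.null(x$true_theta))
    cat("  true theta:", paste(names(x$true_theta), signif(x$true_theta, 4),
                               sep = "=", collapse = ", "),
        if (!is.null(x$seed)) paste("| seed", x$seed), "\n")
  invisible(x)
}

#' Simulate a dataset from a hierarchical model
#'
#' Draws the latent covariates from the spec's latent law, then (for EIV
#' families) the measurements \eqn{W_i | x_i \sim N(x_i, \sigma_1^2)}, then
#' the responses from the response family. Identical
#' `(spec, theta, n, seed)` give bit-identical output; draws are made in the
#' fixed order x, w, y.
#'
#' @param spec a [model_spec()].
#' @param theta named parameter vector, validated by [check_theta()].
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @return an [eiv_data()] object carrying `true_theta` and `seed`.
#' @export
simulate_dataset <- function(spec, theta, n, seed) {
  theta <- check_theta(spec, theta)
  if (!(is.numeric(n) && n >= 1 && n == round(n))) stop("n must be a positive integer")
  set.seed(seed)
  x <- switch(spec$family,
    poisson_quadratic = stats::rnorm(n, theta["beta"], sqrt(spec$quad_latent_var)),
    variance_partition = stats::rnorm(n, theta["mu"], sqrt(theta["tau2"])),
    if (spec$latent == "t") stats::rt(n, spec$latent_df)
    else stats::rnorm(n, 0, spec$latent_sd))
  w <- if (spec$has_covariate_observation) stats::rnorm(n, x, theta["sigma1"])
  eta <- x * if (spec$family %in% eiv_families()) theta["beta"] else 0
  y <- switch(spec$family,
    normal_eiv = stats::rnorm(n, eta, theta["sigma2"]),
    poisson_eiv = stats::rpois(n, exp(pmin(eta, 700))),
    logit_eiv = stats::rbinom(n, 1, stats::plogis(eta)),
    probit_eiv = stats::rbinom(n, 1, stats::pnorm(eta)),
    poisson_quadratic = stats::rpois(n, x^2),
    variance_partition = stats::rnorm(n, x, sqrt(theta["sigma2_obs"])))
  eiv_data(y, w, family = spec$family, true_theta = theta, seed = seed)
}

## ---- per-observation log joint terms and latent derivatives -------------
## x may be a length-n vector or an n-by-m matrix of latent values (columns
## are e.g. quadrature nodes or MCMC clones); y and w are recycled across
## columns. Everything below is vectorised and allocation-light because the
## quadrature, Laplace and MCMC layers all sit on top of it.

## stable Poisson log-pmf on the log-mean scale: y*eta - e^eta - lgamma(y+1)
pois_logpmf_eta <- function(y, eta) {
  ye <- y * eta
  ye[y == 0] <- 0          # avoid 0 * -Inf
  ye - exp(eta) - lgamma(y + 1)
}

log_g_latent <- function(spec, theta, x) {
  switch(spec$family,
    poisson_quadratic = stats::dnorm(x, theta["beta"],
                                     sqrt(spec$quad_latent_var), log = TRUE),
    variance_partition = stats::dnorm(x, theta["mu"], sqrt(theta["tau2"]),
                                      log = TRUE),
    if (spec$latent == "t") stats::dt(x, spec$latent_df, log = TRUE)
    else stats::dnorm(x, 0, spec$latent_sd, log = TRUE))
}

## response + measurement part of the i-th term (the latent prior excluded;
## this is the importance weight when latents are drawn from their prior)
data_loglik_terms <- function(spec, theta, x, data) {
  y <- data$y; w <- data$w
  eta <- x * if (spec$family %in% eiv_families()) theta["beta"] else 0
  ly <- switch(spec$family,
    normal_eiv = stats::dnorm(y, eta, theta["sigma2"], log = TRUE),
    poisson_eiv = pois_logpmf_eta(y, eta),
    logit_eiv = y * stats::plogis(eta, log.p = TRUE) +
      (1 - y) * stats::plogis(-eta, log.p = TRUE),
    probit_eiv = y * stats::pnorm(eta, log.p = TRUE) +
      (1 - y) * stats::pnorm(-eta, log.p = TRUE),
    poisson_quadratic = {
      ll <- y * log(x^2)
      ll[y == 0] <- 0
      ll - x^2 - lgamma(y + 1)
    },
    variance_partition = stats::dnorm(y, x, sqrt(theta["sigma2_obs"]), log = TRUE))
  if (spec$has_covariate_observation)
    ly <- ly + stats::dnorm(w, x, theta["sigma1"], log = TRUE)
  ly
}

## value of the i-th observation's joint log-density term at latent value x
log_terms <- function(spec, theta, x, data) {
  data_loglik_terms(spec, theta, x, data) + log_g_latent(spec, theta, x)
}

## first derivative with respect to x of each observation's term
d1_terms <- function(spec, theta, x, data) {
  y <- data$y; w <- data$w
  beta <- if (spec$family %in% eiv_families()) theta["beta"] else 0
  eta <- x * beta
  dy <- switch(spec$family,
    normal_eiv = beta * (y - eta) / theta["sigma2"]^2,
    poisson_eiv = beta * (y - exp(eta)),
    logit_eiv = beta * (y - stats::plogis(eta)),
    probit_eiv = {
      r1 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE))
      r0 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(-eta, log.p = TRUE))
      beta * (y * r1 - (1 - y) * r0)
    },
    poisson_quadratic = {
      r <- 2 * y / x
      r[y == 0] <- 0
      r - 2 * x
    },
    variance_partition = (y - x) / theta["sigma2_obs"])
  dg <- switch(spec$family,
    poisson_quadratic = -(x - theta["beta"]) / spec$quad_latent_var,
    variance_partition = -(x - theta["mu"]) / theta["tau2"],
    if (spec$latent == "t") {
      df <- spec$latent_df
      -(df + 1) * x / (df + x^2)
    } else -x / spec$latent_sd^2)
  out <- dy + dg
  if (spec$has_covariate_observation) out <- out + (w - x) / theta["sigma1"]^2
  out
}

## second derivative with respect to x of each observation's term
d2_terms <- function(spec, theta, x, data) {
  y <- data$y
  beta <- if (spec$family %in% eiv_families()) theta["beta"] else 0
  eta <- x * beta
  dy <- switch(spec$family,
    normal_eiv = -beta^2 / theta["sigma2"]^2 + 0 * x,
    poisson_eiv = -beta^2 * exp(eta),
    logit_eiv = {
      p <- stats::plogis(eta)
      -beta^2 * p * (1 - p)
    },
    probit_eiv = {
      r1 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE))
      r0 <- exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(-eta, log.p = TRUE))
      beta^2 * (y * (-r1 * (eta + r1)) + (1 - y) * r0 * (eta - r0))
    },
    poisson_quadratic = {
      r <- -2 * y / x^2
      r[y == 0] <- 0
      r - 2
    },
    variance_partition = -1 / theta["sigma2_obs"] + 0 * x)
  dg <- switch(spec$family,
    poisson_quadratic = -1 / spec$quad_latent_var + 0 * x,
    variance_partition = -1 / theta["tau2"] + 0 * x,
    if (spec$latent == "t") {
      df <- spec$latent_df
      -(df + 1) * (df - x^2) / (df + x^2)^2
    } else -1 / spec$latent_sd^2 + 0 * x)
  out <- dy + dg
  if (spec$has_covariate_observation) out <- out - 1 / theta["sigma1"]^2
  out
}

check_latent_dims <- function(x, data) {
  if ((is.matrix(x) && nrow(x) != data$n) || (!is.matrix(x) && length(x) != data$n))
    stop("latent vector length does not match dataset size n = ", data$n)
}

#' Joint log-density of data and latent covariates
#'
#' Returns \eqn{\sum_i [\log f(y_i|x_i;\theta) + \log f(w_i|x_i;\theta) +
#' \log g(x_i;\theta)]}, the w term present only for families with a
#' covariate observation. `-Inf` is returned at support violations (e.g.
#' \eqn{x_i = 0} with \eqn{y_i > 0} under `poisson_quadratic`).
#'
#' @param spec a [model_spec()].
#' @param theta named parameter vector.
#' @param x latent vector of length `data$n`.
#' @param data an [eiv_data()] object.
#' @return scalar log joint density.
#' @export
log_joint <- function(spec, theta, x, data) {
  theta <- check_theta(spec, theta)
  check_latent_dims(x, data)
  sum(log_terms(spec, theta, x, data))
}

#' Gradient of the log joint with respect to the latent vector
#'
#' Because the latents are conditionally independent given \eqn{\theta}, the
#' gradient is the vector of per-observation derivatives and the Hessian is
#' diagonal; [d2log_joint_dx2()] returns that diagonal.
#'
#' @inheritParams log_joint
#' @return length-n numeric vector.
#' @export
dlog_joint_dx <- function(spec, theta, x, data) {
  theta <- check_theta(spec, theta)
  check_latent_dims(x, data)
  d1_terms(spec, theta, x, data)
}

#' @rdname dlog_joint_dx
#' @export
d2log_joint_dx2 <- function(spec, theta, x, data) {
  theta <- check_theta(spec, theta)
  check_latent_dims(x, data)
  d2_terms(spec, theta, x, data)
}
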