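test_that("quadrature matches closed forms where they exist", {
  skip_if_not_installed("mvtnorm")
  # all-Gaussian single observation: marginal is bivariate normal with
  # covariance [[b^2 s0^2 + s2^2, b s0^2], [b s0^2, s0^2 + s1^2]]
  spec <- gaussian_variant()
  th <- c(beta = 1, sigma1 = 1, sigma2 = 1)
  d <- eiv_data(0, 0, family = "normal_eiv")
  expect_equal(quadrature_loglik(spec, th, d),
               mvtnorm::dmvnorm(c(0, 0), sigma = matrix(c(2, 1, 1, 2), 2),
                                log = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
  set.seed(5)
  for (k in 1:5) {
    b <- runif(1, -2, 2); s0 <- runif(1, .5, 2)
    s1 <- runif(1, .5, 2); s2 <- runif(1, .5, 2)
    spec_k <- gaussian_variant(s0)
    th_k <- c(beta = b, sigma1 = s1, sigma2 = s2)
    dk <- simulate_dataset(spec_k, th_k, 12, seed = k)
    S <- matrix(c(b^2 * s0^2 + s2^2, b * s0^2, b * s0^2, s0^2 + s1^2), 2)
    cf <- sum(mvtnorm::dmvnorm(cbind(dk$y, dk$w), sigma = S, log = TRUE))
    expect_equal(quadrature_loglik(spec_k, th_k, dk), cf, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("variance partition marginal equals N(mu, sigma2 + tau2) exactly", {
  spec <- model_spec("variance_partition")
  th <- c(mu = 0.3, sigma2_obs = 1.2, tau2 = 0.7)
  d <- simulate_dataset(spec, th, 25, seed = 5)
  cf <- sum(dnorm(d$y, 0.3, sqrt(1.9), log = TRUE))
  expect_equal(quadrature_loglik(spec, th, d), cf, tolerance = 1e-8,
               ignore_attr = TRUE)
  # ridge flatness: the likelihood depends on the variances only via their sum
  total <- 1.9
  lls <- sapply(seq(0.15, 0.85, length.out = 5), function(s)
    quadrature_loglik(spec, c(mu = 0.3, sigma2_obs = s * total,
                              tau2 = (1 - s) * total), d))
  expect_lt(diff(range(lls)), 1e-6)
})

test_that("fixed-node rule converges and agrees with the adaptive rule", {
  s <- eiv_specs()$poisson
  d <- simulate_dataset(s$spec, s$theta, 25, seed = 3)
  # counts capped: the property under test is quadrature convergence, and
  # astronomically large counts add an irreducible double-precision noise
  # floor of about 1e-3 to every evaluation route
  d$y <- pmin(d$y, 1e3)
  va <- quadrature_loglik(s$spec, s$theta, d, quad_config("adaptive"))
  v2 <- quadrature_loglik(s$spec, s$theta, d, quad_config("fixed_node", 202))
  expect_lt(abs(v2 - va), 1e-4)
  # node doubling on a bounded-response family, where the panel rule is in
  # its geometric-convergence regime
  sl <- eiv_specs()$logit
  dl <- simulate_dataset(sl$spec, sl$theta, 25, seed = 3)
  v1 <- quadrature_loglik(sl$spec, sl$theta, dl, quad_config("fixed_node", 101))
  v2 <- quadrature_loglik(sl$spec, sl$theta, dl, quad_config("fixed_node", 202))
  expect_lt(abs(v1 - v2), 1e-6)
  expect_error(quad_config(node_count = 5), "node_count")
})

test_that("Monte Carlo likelihood agrees with quadrature within its error", {
  set.seed(17)
  inside <- 0; total <- 0
  for (s in eiv_specs()) {
    for (k in 1:5) {
      th <- random_theta(s$spec)
      d <- simulate_dataset(s$spec, th, 8, seed = 100 + k)
      d$y <- pmin(d$y, 1e4)   # keep the prior-sampling estimator in range
      q <- quadrature_loglik(s$spec, th, d)
      m <- mc_loglik(s$spec, th, d, M = 20000, seed = k)
      total <- total + 1
      inside <- inside + (abs(m$value - q) < 3 * m$se)
    }
  }
  expect_gte(inside / total, 0.9)
})

test_that("Monte Carlo standard error scales like M^{-1/2}", {
  s <- eiv_specs()$normal
  d <- simulate_dataset(s$spec, s$theta, 10, seed = 2)
  se1 <- mc_loglik(s$spec, s$theta, d, M = 4000, seed = 9)$se
  se4 <- mc_loglik(s$spec, s$theta, d, M = 16000, seed = 9)$se
  expect_gt(se4 / se1, 0.4)
  expect_lt(se4 / se1, 0.6)
})

test_that("likelihood curves are normalised and symmetric where the model is", {
  # bounded-response family: the simple MC estimator and its delta-method
  # error are both well behaved, so the pointwise 3-SE band is exact
  s <- eiv_specs()$logit
  d <- simulate_dataset(s$spec, s$theta, 20, seed = 11)
  cv <- likelihood_curve(s$spec, d, "beta", seq(-2, 0, length.out = 11),
                         s$theta, methods = c("quadrature", "mc", "laml"),
                         mc_M = 5000)
  for (m in names(cv$relative)) {
    expect_equal(max(cv$relative[[m]], na.rm = TRUE), 1)
    expect_true(all(cv$relative[[m]] > 0 & cv$relative[[m]] <= 1, na.rm = TRUE))
  }
  expect_true(all(abs(cv$loglik$mc - cv$loglik$quadrature) < 3 * cv$se$mc))
  # sign symmetry of the quadratic-mean model
  specq <- model_spec("poisson_quadratic")
  dq <- simulate_dataset(specq, c(beta = 2), 25, seed = 4)
  g <- seq(-3, 3, length.out = 13)
  ll <- sapply(g, function(b) quadrature_loglik(specq, c(beta = b), dq))
  expect_lt(max(abs(ll - rev(ll))), 1e-6)
})

test_that("LR interval inversion recovers the normal-mean closed form", {
  set.seed(3)
  y <- rnorm(40, 0.3, 1)
  ll <- function(m) sum(dnorm(y, m, 1, log = TRUE))
  ci <- lr_confidence_interval(ll, c(-3, 3))
  expect_equal(ci[1], mean(y) - 1.959964 / sqrt(40), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(ci[2], mean(y) + 1.959964 / sqrt(40), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_true(ci[1] <= attr(ci, "estimate") && attr(ci, "estimate") <= ci[2])
  # width shrinks like n^{-1/2} on nested samples
  y4 <- c(y, rnorm(120, 0.3, 1))
  ll4 <- function(m) sum(dnorm(y4, m, 1, log = TRUE))
  ci4 <- lr_confidence_interval(ll4, c(-3, 3))
  expect_gt(diff(ci4) / diff(ci), 0.4)
  expect_lt(diff(ci4) / diff(ci), 0.6)
  # degenerate level spans the whole search range
  ci_all <- lr_confidence_interval(ll, c(-3, 3), level = 1)
  expect_equal(as.numeric(ci_all), c(-3, 3), ignore_attr = TRUE)
})

test_that("oracle profile has the defining profile-likelihood properties", {
  spec <- model_spec("normal_eiv", latent_df = 2,
                     free_parameters = c("beta", "sigma1", "sigma2"))
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  d <- simulate_dataset(spec, th, 15, seed = 6)
  qcfg <- quad_config("fixed_node", node_count = 61)
  grid <- seq(-1.8, 0, length.out = 7)
  prof <- profile_loglik_oracle(spec, d, "beta", grid, th, qcfg)
  # profile dominates any fixed-nuisance slice
  slice <- sapply(grid, function(b)
    quadrature_loglik(spec, c(beta = b, sigma1 = 3, sigma2 = 2), d, qcfg))
  expect_true(all(prof$loglik$quadrature >= slice - 1e-4))
  # single-free-parameter spec: profile is the likelihood curve itself
  spec1 <- model_spec("normal_eiv", latent_df = 2)
  prof1 <- profile_loglik_oracle(spec1, d, "beta", grid, th, qcfg)
  expect_equal(prof1$loglik$quadrature, slice, tolerance = 1e-8)
})
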