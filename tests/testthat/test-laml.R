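test_that("inner modes reproduce the Gaussian conditional mean closed form", {
  spec <- gaussian_variant()
  th <- c(beta = 1, sigma1 = 1, sigma2 = 1)
  d <- simulate_dataset(spec, th, 10, seed = 3)
  im <- inner_modes(spec, th, d)
  cf <- (d$w / 1 + 1 * d$y / 1) / (1 + 1 + 1)
  expect_equal(im$modes, cf, tolerance = 1e-8)
  expect_true(all(im$curvatures < 0))
  # stationarity at the reported modes
  g <- dlog_joint_dx(spec, th, im$modes, d)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("Laplace approximation is exact for Gaussian conditionals", {
  set.seed(21)
  for (k in 1:10) {
    s0 <- runif(1, .5, 2)
    spec <- gaussian_variant(s0)
    th <- c(beta = runif(1, -2, 2), sigma1 = runif(1, .5, 2),
            sigma2 = runif(1, .5, 2))
    d <- simulate_dataset(spec, th, 15, seed = 300 + k)
    expect_equal(as.numeric(laml_loglik(spec, th, d)),
                 quadrature_loglik(spec, th, d), tolerance = 1e-8)
  }
})

test_that("multistart finds both latent modes of the quadratic-mean model", {
  spec <- model_spec("poisson_quadratic")
  th <- c(beta = 0.3)
  d <- eiv_data(c(9, 16), family = "poisson_quadratic")
  im <- inner_modes(spec, th, d, inner_config("multistart"))
  expect_true(all(im$n_modes >= 2))
  # grid-scan oracle: both detected optima are genuine local maxima
  xs <- seq(-6, 6, length.out = 2001)
  for (i in 1:2) {
    ll <- log_terms(spec, th, xs, list(y = rep(d$y[i], 2001), w = NULL,
                                       n = 2001))
    top <- xs[which.max(ll)]
    expect_equal(abs(im$modes[i]), abs(top), tolerance = 1e-2)
  }
})

test_that("single-dataset slope fit is stable and reproducible", {
  spec <- model_spec("normal_eiv", latent_df = 2)
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  d <- simulate_dataset(spec, th, 50, seed = 7)
  f1 <- laml_mle(spec, d, th)
  th2 <- th; th2["beta"] <- -0.4
  f2 <- laml_mle(spec, d, th2)
  expect_equal(f1$theta_hat["beta"], f2$theta_hat["beta"], tolerance = 1e-5)
  f3 <- laml_mle(spec, d, th)
  expect_identical(f1$theta_hat, f3$theta_hat)
  expect_identical(f1$loglik, f3$loglik)
  expect_true(all(f1$inner_curvatures < 0))
})

test_that("Laplace and exact maximisers separate under heavy-tailed latents", {
  # the disagreement configuration: curve maxima land in different places
  spec <- model_spec("normal_eiv", latent_df = 2)
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  d <- simulate_dataset(spec, th, 50, seed = 7)
  qcfg <- quad_config("fixed_node", node_count = 101)
  f_q <- function(b) quadrature_loglik(spec, c(beta = b, sigma1 = 3,
                                               sigma2 = 2), d, qcfg)
  ci_q <- lr_confidence_interval(f_q, c(-4, 2))
  fit_l <- laml_mle(spec, d, th)
  expect_gt(abs(fit_l$theta_hat["beta"] - attr(ci_q, "estimate")), 0.1)
})

test_that("Laplace profile reduces to the curve with a single free parameter", {
  spec <- model_spec("normal_eiv", latent_df = 2)
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  d <- simulate_dataset(spec, th, 20, seed = 9)
  grid <- seq(-1.6, -0.2, length.out = 6)
  prof <- profile_laml(spec, d, "beta", grid, th)
  slice <- sapply(grid, function(b)
    laml_loglik(spec, c(beta = b, sigma1 = 3, sigma2 = 2), d))
  expect_equal(prof$loglik$laml, slice, tolerance = 1e-8)
})

test_that("gaussian-variant profiles of the two objectives coincide", {
  spec <- model_spec("normal_eiv", latent = "normal", latent_sd = 1,
                     free_parameters = c("beta", "sigma2"))
  th <- c(beta = 1, sigma1 = 1, sigma2 = 1)
  d <- simulate_dataset(spec, th, 15, seed = 12)
  grid <- seq(0.4, 1.6, length.out = 5)
  qcfg <- quad_config("fixed_node", node_count = 61)
  po <- profile_loglik_oracle(spec, d, "beta", grid, th, qcfg)
  pl <- profile_laml(spec, d, "beta", grid, th)
  expect_equal(pl$loglik$laml, po$loglik$quadrature, tolerance = 1e-4)
})
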