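test_that("bias factors are identically one for Gaussian conditionals", {
  set.seed(9)
  for (k in 1:5) {
    spec <- gaussian_variant(runif(1, .5, 2))
    th <- c(beta = runif(1, -2, 2), sigma1 = runif(1, .5, 2),
            sigma2 = runif(1, .5, 2))
    d <- simulate_dataset(spec, th, 6, seed = 40 + k)
    b <- sapply(seq_len(d$n), function(i) bias_factor_exact(spec, th, d, i))
    expect_lt(max(abs(b - 1)), 1e-6)
  }
})

test_that("summed log bias factors equal the Laplace-minus-exact gap", {
  set.seed(27)
  for (s in eiv_specs()) {
    for (k in 1:3) {
      th <- random_theta(s$spec)
      d <- simulate_dataset(s$spec, th, 8, seed = 200 + k)
      lb <- log(lamlbias:::bias_factors_exact(s$spec, th, d))
      gap <- as.numeric(laml_loglik(s$spec, th, d)) -
        quadrature_loglik(s$spec, th, d)
      expect_lt(abs(sum(lb) - gap), 1e-6)
      expect_true(all(is.finite(lb)))
    }
  }
})

test_that("KDE mode estimator recovers known standard-normal quantities", {
  set.seed(14)
  draws <- rnorm(40000)
  est <- lamlbias:::kde_mode_bias(draws)
  expect_lt(abs(est$density_at_mode - 1 / sqrt(2 * pi)) * sqrt(2 * pi), 0.1)
  expect_lt(abs(est$curvature + 1), 0.25)
  expect_lt(abs(est$b - 1), 0.1)
  expect_error(lamlbias:::kde_mode_bias(rep(1, 500)), "point mass")
})

test_that("MCMC route to the bias factor agrees with the exact route", {
  spec <- eiv_specs()$normal$spec
  th <- eiv_specs()$normal$theta
  d <- simulate_dataset(spec, th, 5, seed = 9)
  be <- bias_factor_exact(spec, th, d, 2)
  bm <- bias_factor_mcmc(spec, th, d, 2,
                         chain_config(iterations = 24000, burn_in = 3000,
                                      seed = 6))
  expect_lt(abs(bm$value - be), 3 * bm$se + 0.15 * be)
  expect_gt(bm$value, 0)
})

test_that("bias profile is flat for Gaussians and shrinks with tamer tails", {
  spec_g <- gaussian_variant()
  th_g <- c(beta = 1, sigma1 = 1, sigma2 = 1)
  d_g <- simulate_dataset(spec_g, th_g, 4, seed = 2)
  bp <- bias_profile(spec_g, d_g, 1, seq(0.5, 1.5, length.out = 5), th_g)
  expect_lt(max(abs(bp$bias_exact - 1)), 1e-6)
  # heavy (df=2) versus near-Gaussian (df=10) latent tails, same data seed
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  grid <- seq(-2, 0, length.out = 9)
  spec2 <- model_spec("normal_eiv", latent_df = 2)
  spec10 <- model_spec("normal_eiv", latent_df = 10)
  d2 <- simulate_dataset(spec2, th, 30, seed = 5)
  d10 <- simulate_dataset(spec10, th, 30, seed = 5)
  b2 <- bias_profile(spec2, d2, 1, grid, th)
  b10 <- bias_profile(spec10, d10, 1, grid, th)
  expect_gt(diff(range(log(b2$bias_exact))), 0)  # varies with the slope
  expect_lt(max(abs(log(b10$bias_exact))), max(abs(log(b2$bias_exact))))
})

test_that("MCMC bias profile mimics the exact profile's shape", {
  spec <- eiv_specs()$poisson$spec
  th <- eiv_specs()$poisson$theta
  d <- simulate_dataset(spec, th, 10, seed = 3)
  d$y <- pmin(d$y, 50)
  grid <- seq(-2, -0.2, length.out = 10)
  # profile the observation whose bias factor varies most over the grid
  # (a near-constant profile has no shape for the noisy route to recover)
  rng <- sapply(seq_len(d$n), function(i)
    diff(range(log(bias_profile(spec, d, i, grid, th)$bias_exact))))
  i <- which.max(rng)
  bp <- bias_profile(spec, d, i, grid, th, with_mcmc = TRUE,
                     chain_cfg = chain_config(iterations = 12000,
                                              burn_in = 2000, seed = 7))
  ok <- is.finite(bp$bias_mcmc)
  expect_gte(sum(ok), 8)
  expect_gt(cor(bp$bias_exact[ok], bp$bias_mcmc[ok]), 0.9)
  expect_gt(cor(bp$bias_exact[ok], bp$bias_mcmc[ok], method = "spearman"),
            0.5)
})
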