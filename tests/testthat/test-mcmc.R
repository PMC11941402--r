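test_that("conditional latent sampler recovers Gaussian conditional moments", {
  spec <- gaussian_variant()
  th <- c(beta = 1, sigma1 = 1, sigma2 = 1)
  d <- simulate_dataset(spec, th, 12, seed = 4)
  ch <- sample_conditional_latent(spec, th, d,
                                  chain_config(iterations = 4000,
                                               burn_in = 1000, seed = 2))
  m_cf <- (d$w + d$y) / 3
  s_cf <- sqrt(1 / 3)
  mc_se <- s_cf / sqrt(pmax(ch$ess, 10))
  expect_true(all(abs(colMeans(ch$draws) - m_cf) < 3.5 * mc_se))
  expect_true(all(abs(apply(ch$draws, 2, sd) - s_cf) < 0.08))
  expect_true(all(ch$rhat < 1.1, na.rm = TRUE))
  # frozen adaptation keeps acceptance in a sane band
  expect_true(all(ch$acceptance_rate > 0.15 & ch$acceptance_rate < 0.65))
})

test_that("chains are reproducible under the same seed and stationary", {
  spec <- eiv_specs()$poisson$spec
  th <- eiv_specs()$poisson$theta
  d <- simulate_dataset(spec, th, 8, seed = 10)
  d$y <- pmin(d$y, 100)
  cfg <- chain_config(iterations = 3000, burn_in = 800, seed = 5)
  ch1 <- sample_conditional_latent(spec, th, d, cfg)
  ch2 <- sample_conditional_latent(spec, th, d, cfg)
  expect_identical(ch1$draws, ch2$draws)
  # doubling iterations leaves the estimated means within Monte Carlo error
  ch3 <- sample_conditional_latent(spec, th, d,
                                   chain_config(iterations = 6000,
                                                burn_in = 800, seed = 5))
  se <- apply(ch1$draws, 2, sd) / sqrt(pmax(ch1$ess, 10))
  expect_true(all(abs(colMeans(ch1$draws) - colMeans(ch3$draws)) < 4 * se))
})

test_that("a single chain concentrates in one latent mode of the bimodal model", {
  spec <- model_spec("poisson_quadratic")
  th <- c(beta = 0)
  d <- eiv_data(25, family = "poisson_quadratic")  # modes near +5 and -5
  ch <- suppressWarnings(sample_conditional_latent(
    spec, th, d, chain_config(iterations = 4000, burn_in = 1000,
                              seed = 3, n_chains = 1)))
  signs <- sign(ch$draws[abs(ch$draws) > 1])
  expect_gt(max(mean(signs > 0), mean(signs < 0)), 0.95)
})

test_that("data-cloning posterior matches the conjugate normal closed form", {
  # variances fixed at 0.5 + 0.5 make the marginal y ~ N(mu, 1), so the
  # K-clone posterior for mu under a N(0, 10^2) prior is known exactly
  spec <- model_spec("variance_partition", free_parameters = "mu")
  th <- c(mu = 0.4, sigma2_obs = 0.5, tau2 = 0.5)
  d <- simulate_dataset(spec, th, 25, seed = 8)
  for (K in c(1, 20)) {
    ch <- sample_dc_posterior(spec, d, K, prior = list(mean = 0, sd = 10),
                              chain_config(iterations = 6000, burn_in = 1500,
                                           seed = 3), theta_init = th)
    prec <- 25 * K + 1 / 100
    post_mean <- sum(d$y) * K / prec
    post_var <- 1 / prec
    mc_se <- sqrt(post_var / max(min(ch$ess), 20))
    expect_lt(abs(mean(ch$draws) - post_mean), 3 * mc_se)
    expect_lt(abs(var(ch$draws[, 1]) - post_var) / post_var, 0.25)
  }
})

test_that("clone variance scaling is 1/K for an identifiable slope", {
  spec <- model_spec("normal_eiv", latent_df = 2)
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  d <- simulate_dataset(spec, th, 30, seed = 13)
  sv <- sapply(c(1, 4, 16), function(K) {
    ch <- sample_dc_posterior(spec, d, K,
                              cfg = chain_config(iterations = 5000,
                                                 burn_in = 1200, seed = 6),
                              theta_init = th)
    K * var(ch$draws[, 1])
  })
  expect_lt(max(sv) / min(sv), 3)
})
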