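test_that("data-cloning MLE recovers the conjugate normal closed form", {
  spec <- model_spec("variance_partition", free_parameters = "mu")
  th <- c(mu = 0.4, sigma2_obs = 0.5, tau2 = 0.5)
  d <- simulate_dataset(spec, th, 25, seed = 8)
  fit <- dc_mle(spec, d, K_schedule = c(1, 5, 20),
                cfg = chain_config(iterations = 6000, burn_in = 1500,
                                   seed = 3), theta_init = th)
  expect_lt(abs(fit$theta_hat["mu"] - mean(d$y)), 3 * fit$mc_se["mu"] + 0.01)
  # K * posterior variance estimates the inverse Fisher information 1/n
  expect_lt(abs(fit$fisher_var["mu"] - 1 / 25) / (1 / 25), 0.25)
})

test_that("clone-scaling diagnostic separates the three variance regimes", {
  mk <- function(K, v) structure(list(K = K, posterior_mean = c(p = 0),
                                      posterior_var = c(p = v),
                                      scaled_var = c(p = K * v)),
                                 class = "clone_run")
  decaying <- Map(mk, c(1, 5, 20), 0.8 / c(1, 5, 20))
  expect_equal(unname(identifiability_diagnostic(decaying)["p"]),
               "identifiable")
  constant <- Map(mk, c(1, 5, 20), c(0.8, 0.79, 0.81))
  expect_equal(unname(identifiability_diagnostic(constant)["p"]),
               "nonidentifiable")
  partial <- Map(mk, c(1, 5, 20), 0.4 + 0.4 / c(1, 5, 20))
  expect_equal(unname(identifiability_diagnostic(partial)["p"]),
               "inconclusive")
  expect_error(identifiability_diagnostic(decaying[1:2]), "3 clone levels")
})

test_that("DC slope estimate matches the exact-likelihood maximiser", {
  spec <- model_spec("normal_eiv", latent_df = 2)
  th <- c(beta = -1, sigma1 = 3, sigma2 = 2)
  d <- simulate_dataset(spec, th, 40, seed = 13)
  fit <- dc_mle(spec, d, K_schedule = c(1, 5, 20),
                cfg = chain_config(iterations = 6000, burn_in = 1500,
                                   seed = 21), theta_init = th)
  qf <- function(b) quadrature_loglik(spec, c(beta = b, sigma1 = 3,
                                              sigma2 = 2), d,
                                      quad_config("fixed_node", 61))
  ci <- lr_confidence_interval(qf, c(-4, 2))
  oracle_se <- diff(ci) / (2 * 1.959964)
  expect_lt(abs(fit$theta_hat["beta"] - attr(ci, "estimate")), 2 * oracle_se)
  expect_equal(unname(identifiability_diagnostic(fit$runs)["beta"]),
               "identifiable")
})
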