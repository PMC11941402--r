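test_that("coverage accounting always balances hits, misses and failures", {
  cfgs <- list(list(label = "nn", spec = model_spec("normal_eiv", latent_df = 2),
                    theta_true = c(beta = -1, sigma1 = 3, sigma2 = 2)))
  res <- run_coverage_study(cfgs, reps = 6, n = 15, root_seed = 3,
                            quad_cfg = quad_config("fixed_node", 61))
  expect_length(res, 2)
  for (r in res) {
    tab <- r$per_replicate
    misses <- sum(!tab$covered, na.rm = TRUE)
    expect_equal(r$hits + misses + r$failures, r$reps)
    expect_equal(r$binom_se, sqrt(r$coverage * (1 - r$coverage) / r$reps))
    expect_true(r$coverage >= 0 && r$coverage <= 1)
  }
})

test_that("degenerate nominal level gives full coverage", {
  cfgs <- list(list(label = "nn", spec = model_spec("normal_eiv", latent_df = 2),
                    theta_true = c(beta = -1, sigma1 = 3, sigma2 = 2),
                    methods = "oracle_lr"))
  res <- run_coverage_study(cfgs, reps = 3, n = 10, root_seed = 5, level = 1,
                            quad_cfg = quad_config("fixed_node", 61))
  expect_equal(res[[1]]$coverage, 1)
})

test_that("curve comparison reports per-method maximisers and intervals", {
  spec <- model_spec("normal_eiv", latent_df = 2)
  out <- run_curve_comparison(spec, c(beta = -1, sigma1 = 3, sigma2 = 2),
                              n = 25, seed = 7,
                              grid = seq(-2.5, 0.5, length.out = 21),
                              methods = c("quadrature", "laml"),
                              quad_cfg = quad_config("fixed_node", 61))
  expect_s3_class(out$curve, "likelihood_curve")
  expect_named(out$summary, c("quadrature", "laml"))
  ci <- out$summary$quadrature$ci
  expect_true(ci[1] < attr(ci, "estimate") && attr(ci, "estimate") < ci[2])
  df <- as.data.frame(out$curve)
  expect_true(all(c("parameter", "value", "method", "loglik", "relative") %in%
                    names(df)))
})

test_that("profile comparison flags the off-centre Laplace profile", {
  spec <- model_spec("normal_eiv", latent_df = 2,
                     free_parameters = c("beta", "sigma1", "sigma2"))
  out <- run_profile_comparison(spec, c(beta = -1, sigma1 = 3, sigma2 = 2),
                                n = 40, seed = 3,
                                psi_grid = seq(-2, 0.2, length.out = 12),
                                quad_cfg = quad_config("fixed_node", 61))
  s <- out$summary
  expect_equal(s$argmax_oracle,
               out$oracle$grid[which.max(out$oracle$loglik$quadrature)])
  expect_type(s$centered, "logical")
  expect_false(s$centered)   # the heavy-tail disagreement configuration
})

test_that("quadratic-mean report detects the bimodal/unimodal contrast", {
  rq <- run_nonidentifiable_quadratic(beta_true = 2, n = 40, seed = 5,
                                      grid = seq(-4, 4, length.out = 33),
                                      with_gt = FALSE, with_dc = FALSE)
  expect_lt(rq$oracle_symmetry_error, 1e-6)
  expect_gte(rq$oracle_n_modes, 2)
  expect_equal(rq$laml_n_modes, 1)
  expect_true(rq$bimodality_detected[["oracle"]])
  expect_false(rq$bimodality_detected[["laml"]])
})

test_that("variance-partition report shows the ridge and start sensitivity", {
  rv <- run_nonidentifiable_variance(n = 40, seed = 5, with_dc = FALSE)
  expect_lt(rv$ridge_flatness_error, 1e-6)
  expect_gte(sum(!vapply(rv$fits, is.null, TRUE)), 2)
  expect_gt(rv$max_curve_discrepancy, 0.2)
})
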