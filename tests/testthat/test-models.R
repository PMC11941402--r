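test_that("simulator is deterministic and respects family support", {
  for (s in all_specs()) {
    d1 <- simulate_dataset(s$spec, s$theta, 30, seed = 7)
    d2 <- simulate_dataset(s$spec, s$theta, 30, seed = 7)
    expect_identical(d1$y, d2$y)
    expect_identical(d1$w, d2$w)
    d3 <- simulate_dataset(s$spec, s$theta, 30, seed = 8)
    expect_false(identical(d1$y, d3$y))
    if (s$spec$family %in% c("poisson_eiv", "poisson_quadratic")) {
      expect_true(all(d1$y >= 0 & d1$y == round(d1$y)))
    }
    if (s$spec$family %in% c("logit_eiv", "probit_eiv"))
      expect_true(all(d1$y %in% c(0, 1)))
    expect_equal(d1$n, 30)
    expect_equal(is.null(d1$w), !s$spec$has_covariate_observation)
  }
})

test_that("invalid parameters and sizes are rejected at construction", {
  spec <- model_spec("normal_eiv")
  expect_error(check_theta(spec, c(beta = 1, sigma1 = -1, sigma2 = 1)),
               "strictly positive")
  expect_error(check_theta(spec, c(beta = 1, sigma1 = 1)), "names")
  expect_error(simulate_dataset(spec, c(beta = 1, sigma1 = 1, sigma2 = 1), 0, 1),
               "positive integer")
  expect_error(eiv_data(c(0, 1, 2.5), family = "poisson_eiv"), "integer")
  expect_error(eiv_data(c(0, 2), family = "logit_eiv"), "0, 1")
})

test_that("simulated responses match the moments of the generative law", {
  spec <- model_spec("normal_eiv", latent_df = 10)
  th <- c(beta = 0, sigma1 = 1, sigma2 = 1)
  d <- simulate_dataset(spec, th, 20000, seed = 42)
  # beta = 0: y is pure N(0, sigma2^2) noise
  expect_lt(abs(mean(d$y)), 4 / sqrt(20000))
  expect_lt(abs(var(d$y) - 1), 0.05)
  # w = x + noise: var(w) = Var(T10) + sigma1^2 = 10/8 + 1
  expect_lt(abs(var(d$w) - (10 / 8 + 1)) / (10 / 8 + 1), 0.1)
})

test_that("log joint is the sum of closed-form component densities", {
  spec <- model_spec("normal_eiv", latent_df = 2)
  th <- c(beta = 0, sigma1 = 1, sigma2 = 1)
  d <- eiv_data(0, 0, family = "normal_eiv")
  expect_equal(log_joint(spec, th, 0, d),
               dnorm(0, log = TRUE) * 2 + dt(0, 2, log = TRUE))
  # additivity over independent observations
  d2 <- eiv_data(c(0.4, -1), c(0.2, 0.5), family = "normal_eiv")
  x <- c(0.1, -0.3)
  expect_equal(log_joint(spec, th, x, d2),
               log_joint(spec, th, x[1], eiv_data(0.4, 0.2)) +
                 log_joint(spec, th, x[2], eiv_data(-1, 0.5)))
  # Poisson pmf at zero contributes -lambda
  specp <- model_spec("poisson_eiv", latent_df = 2)
  thp <- c(beta = 1, sigma1 = 1)
  dp <- eiv_data(0, 0.5, family = "poisson_eiv")
  expect_equal(log_joint(specp, thp, 0.7, dp),
               -exp(0.7) + dnorm(0.5, 0.7, 1, log = TRUE) + dt(0.7, 2, log = TRUE))
  expect_error(log_joint(spec, th, c(0, 1), d), "length")
})

test_that("analytic latent derivatives match finite differences", {
  skip_if_not_installed("numDeriv")
  set.seed(31)
  for (s in all_specs()) {
    for (rep in 1:4) {
      th <- random_theta(s$spec)
      d <- simulate_dataset(s$spec, th, 8, seed = rep)
      # tame extreme counts so the finite-difference oracle stays in a
      # numerically comparable range
      if (s$spec$family %in% c("poisson_eiv", "poisson_quadratic"))
        d$y <- pmin(d$y, 50)
      x <- rnorm(8, 0.6, 0.7)
      g <- dlog_joint_dx(s$spec, th, x, d)
      h <- d2log_joint_dx2(s$spec, th, x, d)
      for (i in c(1, 5, 8)) {
        f <- function(xi) { xx <- x; xx[i] <- xi; log_joint(s$spec, th, xx, d) }
        expect_equal(g[i], numDeriv::grad(f, x[i]), tolerance = 1e-5,
                     ignore_attr = TRUE)
        expect_equal(h[i], numDeriv::hessian(f, x[i])[1, 1], tolerance = 1e-4,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("datasets round-trip through CSV with a JSON sidecar", {
  spec <- model_spec("poisson_eiv", latent_df = 2)
  d <- simulate_dataset(spec, c(beta = -1, sigma1 = 3), 20, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(d2$y, d$y)
  expect_equal(d2$w, d$w)
  expect_equal(d2$family, d$family)
  expect_equal(unname(d2$true_theta), unname(d$true_theta), tolerance = 1e-12)
  expect_equal(d2$seed, d$seed)
  unlink(c(path, paste0(path, ".json")))
})
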