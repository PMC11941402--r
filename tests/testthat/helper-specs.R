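# shared builders for the model specs exercised throughout the suite

gaussian_variant <- function(latent_sd = 1)
  model_spec("normal_eiv", latent = "normal", latent_sd = latent_sd)

eiv_specs <- function() list(
  normal = list(spec = model_spec("normal_eiv", latent_df = 2),
                theta = c(beta = -1, sigma1 = 3, sigma2 = 2)),
  poisson = list(spec = model_spec("poisson_eiv", latent_df = 2),
                 theta = c(beta = -1, sigma1 = 3)),
  logit = list(spec = model_spec("logit_eiv", latent_df = 10),
               theta = c(beta = -1, sigma1 = 3)),
  probit = list(spec = model_spec("probit_eiv", latent_df = 10),
                theta = c(beta = -1, sigma1 = 3)))

# random parameter draw inside the constraint box of a family
random_theta <- function(spec) {
  th <- switch(spec$family,
    normal_eiv = c(beta = stats::runif(1, -2, 2),
                   sigma1 = stats::runif(1, 0.5, 3),
                   sigma2 = stats::runif(1, 0.5, 3)),
    poisson_eiv = c(beta = stats::runif(1, -1.5, 0.5),
                    sigma1 = stats::runif(1, 0.5, 3)),
    logit_eiv = ,
    probit_eiv = c(beta = stats::runif(1, -2, 2),
                   sigma1 = stats::runif(1, 0.5, 3)),
    poisson_quadratic = c(beta = stats::runif(1, -3, 3)),
    variance_partition = c(mu = stats::runif(1, -1, 1),
                           sigma2_obs = stats::runif(1, 0.3, 2),
                           tau2 = stats::runif(1, 0.3, 2)))
  th
}

all_specs <- function() c(
  eiv_specs(),
  list(quadratic = list(spec = model_spec("poisson_quadratic"),
                        theta = c(beta = 2)),
       varpart = list(spec = model_spec("variance_partition"),
                      theta = c(mu = 0, sigma2_obs = 1, tau2 = 1))))
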