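test_that("Gaussian flavor recovers coefficients from Gaussian data", {
  # data generated from the model MoNN assumes: normal REs and errors
  set.seed(31)
  m <- 50; tt <- 0:10
  B <- natural_cubic_basis(rep(tt, m), spline_spec(n_interior = 2))
  Zb <- cbind(rbinom(m, 1, 0.24), rbinom(m, 1, 0.44))
  phi <- matrix(rnorm(m * 4, sd = sqrt(0.5)), m, 4)
  subj <- rep(seq_len(m), each = length(tt))
  y <- 27.5 - 5 * Zb[subj, 1] - 4 * Zb[subj, 2] + phi[subj, 1] +
    rowSums(B * (matrix(c(-9, -25, -5), m * 11, 3, byrow = TRUE) +
                   phi[subj, -1])) + rnorm(m * 11, sd = sqrt(0.5))
  dat <- longitudinal_data(
    data.frame(subject = subj, time = rep(tt, m), response = y,
               Z1 = Zb[subj, 1], Z2 = Zb[subj, 2]),
    covariates = c("Z1", "Z2"))
  cfg <- model_config("normal", "normal", fixed_covariates = c("Z1", "Z2"),
                      mcmc = mcmc_control(chains = 1, iter = 1500,
                                          burnin = 500, thin = 2, seed = 44))
  fit <- run_mcmc(dat, cfg)
  s <- posterior_summary(fit)
  truth <- c(27.5, -5, -4, -9, -25, -5)
  rows <- match(paste0("alpha[", fit$bundle$z_names, "]"), s$parameter)
  expect_true(all(abs(s$mean[rows] - truth) < 3 * s$sd[rows]))
})

test_that("the sampler is reproducible and chains are exchangeable", {
  sim <- simulate_dataset(sim_design(m = 20), seed = 5)
  cfg <- model_config("skew_t", "skew_t", fixed_covariates = c("Z1", "Z2"),
                      mcmc = mcmc_control(chains = 2, iter = 300,
                                          burnin = 100, thin = 1, seed = 11))
  f1 <- run_mcmc(sim$data, cfg)
  f2 <- run_mcmc(sim$data, cfg)
  expect_identical(f1$draws, f2$draws)

  fa <- run_mcmc(sim$data, cfg, chain_seeds = c(101L, 202L))
  fb <- run_mcmc(sim$data, cfg, chain_seeds = c(202L, 101L))
  expect_identical(fa$draws[[1]], fb$draws[[2]])
  expect_identical(fa$draws[[2]], fb$draws[[1]])
})

test_that("prior-only runs reproduce the prior moments", {
  b <- empty_bundle(m = 30, p = 1, d = 1)
  cfg <- model_config("skew_normal", "skew_normal", center = FALSE,
                      mcmc = mcmc_control(chains = 1, iter = 2500,
                                          burnin = 500, thin = 1, seed = 3))
  pr <- prior_spec(sigma2_shape = 3, sigma2_rate = 2, kappa_delta_eps = 4)
  fit <- run_mcmc(b, cfg, priors = pr)
  pool <- as.matrix(fit)
  # sigma2_eps ~ IG(3, 2): mean 1, sd 1; delta_eps ~ N(0, 4)
  expect_equal(mean(pool[, "sigma2_eps"]), 1, tolerance = 0.15)
  expect_equal(mean(pool[, "delta_eps"]), 0, tolerance = 0.2)
  expect_equal(sd(pool[, "delta_eps"]), 2, tolerance = 0.2)
})

test_that("general machinery matches a directly coded normal-normal Gibbs sampler", {
  set.seed(32)
  m <- 40; ni <- 5
  subj <- rep(seq_len(m), each = ni)
  x <- rnorm(m * ni)
  bint <- rnorm(m, sd = 0.8)
  y <- 2 + 1.5 * x + bint[subj] + rnorm(m * ni, sd = 0.7)
  b <- manual_bundle(y, subj, cbind(`(Intercept)` = 1, x = x))
  cfg <- model_config("normal", "normal",
                      mcmc = mcmc_control(chains = 1, iter = 4000,
                                          burnin = 1000, thin = 1, seed = 17))
  fit <- run_mcmc(b, cfg)
  pool <- as.matrix(fit)
  oracle <- direct_nn_gibbs(y, cbind(1, x), subj, 4000, 1000, seed = 18)
  expect_equal(mean(pool[, "alpha[(Intercept)]"]), mean(oracle[, "beta1"]),
               tolerance = 0.05)
  expect_equal(mean(pool[, "alpha[x]"]), mean(oracle[, "beta2"]),
               tolerance = 0.05)
  expect_equal(mean(pool[, "sigma2_eps"]), mean(oracle[, "sigma2"]),
               tolerance = 0.05)
  expect_equal(mean(pool[, "Sigma_phi[1,1]"]), mean(oracle[, "tau2"]),
               tolerance = 0.15)
})

test_that("dof acceptance lands in a healthy range after adaptation", {
  sim <- simulate_dataset(sim_design(m = 60), seed = 9)
  cfg <- model_config("skew_t", "skew_t", fixed_covariates = c("Z1", "Z2"),
                      mcmc = mcmc_control(chains = 1, iter = 1500,
                                          burnin = 700, thin = 2, seed = 21))
  fit <- run_mcmc(sim$data, cfg)
  expect_true(all(fit$acceptance[1, ] > 0.1 & fit$acceptance[1, ] < 0.7))
  pool <- as.matrix(fit)
  expect_true(all(pool[, "rho_eps"] > 3))
  expect_true(all(pool[, "rho_phi"] > 3))
  expect_equal(nrow(pool), (1500 - 700) %/% 2)
})

test_that("flavor-pinned parameters are absent from the recorded draws", {
  sim <- simulate_dataset(sim_design(m = 30), seed = 10)
  mk <- function(lab) run_mcmc(sim$data, config_from_label(
    lab, fixed_covariates = c("Z1", "Z2"),
    mcmc = mcmc_control(chains = 1, iter = 120, burnin = 40, thin = 1, seed = 2)))
  expect_false(any(c("delta_eps", "rho_eps", "rho_phi") %in% mk("MoNN")$params))
  expect_true(all(c("delta_eps", "rho_eps") %in% mk("MoNST")$params))
  expect_false("rho_phi" %in% mk("MoSNSN")$params)
  expect_true(all(c("rho_phi", "rho_eps") %in% mk("MoSTST")$params))
})
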