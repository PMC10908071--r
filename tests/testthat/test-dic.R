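test_that("conditional deviance matches the closed-form normal likelihood", {
  set.seed(51)
  n <- 15
  y <- rnorm(n, 1, 2)
  b <- manual_bundle(y, rep(1:3, each = 5), matrix(1, n, 1))
  cfg <- model_config("normal", "normal")
  st <- initialize_state(b, cfg, seed = 1)
  st$alpha <- 0.7
  st$phi <- matrix(c(0.2, -0.1, 0.5), 3, 1)
  st$sigma2_eps <- 1.3
  mu <- 0.7 + st$phi[rep(1:3, each = 5), 1]
  dev_hand <- -2 * sum(dnorm(y, mu, sqrt(1.3), log = TRUE))
  expect_equal(deviance_state(st, b, cfg), dev_hand, tolerance = 1e-10)

  # doubling the variance changes the deviance by the analytic amount
  st2 <- st
  st2$sigma2_eps <- 2.6
  delta <- n * log(2) + sum((y - mu)^2) / 2.6 - sum((y - mu)^2) / 1.3
  expect_equal(deviance_state(st2, b, cfg) - deviance_state(st, b, cfg),
               delta, tolerance = 1e-10)
})

test_that("a point mass at the conditional mean with variance 1/(2*pi) has zero deviance", {
  b <- manual_bundle(3.4, 1, matrix(1, 1, 1))
  cfg <- model_config("normal", "normal")
  st <- initialize_state(b, cfg, seed = 2)
  st$alpha <- 3.4
  st$phi <- matrix(0, 1, 1)
  st$sigma2_eps <- 1 / (2 * pi)
  expect_equal(deviance_state(st, b, cfg), 0, tolerance = 1e-12)
})

test_that("DIC identities hold by construction", {
  r <- compute_dic(mean_dev = 120, dev_at_mean = 100)
  expect_equal(r$p_d, 20, tolerance = 1e-12)
  expect_equal(r$dic, r$dev_at_mean + 2 * r$p_d, tolerance = 1e-12)
  expect_equal(r$p_d, r$mean_dev - r$dev_at_mean, tolerance = 1e-12)

  r0 <- compute_dic(mean_dev = 100, dev_at_mean = 100)
  expect_equal(r0$p_d, 0)
  expect_equal(r0$dic, 100)
})

test_that("effective parameters are about one for the normal-mean model", {
  # y ~ N(mu, 1) with n = 100 and an effectively flat prior: p_d ~ 1
  set.seed(52)
  pds <- vapply(1:5, function(i) {
    y <- rnorm(100, 3, 1)
    draws <- rnorm(5000, mean(y), sqrt(1 / 100))
    devs <- vapply(draws, function(mu) -2 * sum(dnorm(y, mu, 1, log = TRUE)), 0)
    compute_dic(mean(devs),
                -2 * sum(dnorm(y, mean(draws), 1, log = TRUE)))$p_d
  }, 0)
  expect_true(all(abs(pds - 1) < 0.2))
})

test_that("a single retained draw gives zero effective parameters", {
  # with one retained state the posterior 'means' equal that state, so the
  # R-side deviance at the mean must equal the C++ deviance of the draw
  sim <- simulate_dataset(sim_design(m = 10), seed = 14)
  for (lab in c("MoNN", "MoSTST")) {
    cfg <- config_from_label(lab, fixed_covariates = c("Z1", "Z2"),
                             mcmc = mcmc_control(chains = 1, iter = 101,
                                                 burnin = 100, thin = 1, seed = 7))
    fit <- run_mcmc(sim$data, cfg)
    expect_equal(nrow(as.matrix(fit)), 1L)
    r <- dic(fit)
    expect_equal(r$p_d, 0, tolerance = 1e-8)
  }
})

test_that("DIC is insensitive to the thinning interval on a fixed trajectory", {
  sim <- simulate_dataset(sim_design(m = 20), seed = 15)
  base <- mcmc_control(chains = 1, iter = 1200, burnin = 400, thin = 2, seed = 9)
  cfg <- model_config("normal", "normal", fixed_covariates = c("Z1", "Z2"),
                      mcmc = base)
  f2 <- run_mcmc(sim$data, cfg)
  thick <- base; thick$thin <- 8L
  f8 <- run_mcmc(sim$data, cfg, mcmc = thick)
  d2 <- dic(f2); d8 <- dic(f8)
  mcse <- sd(as.matrix(f2)[, "deviance"]) / sqrt(100)
  expect_lt(abs(d2$dic - d8$dic), 6 * mcse + 2)
})

test_that("the Gaussian flavor has the largest DIC on skewed data", {
  sim <- simulate_dataset(sim_design(m = 80), seed = 16)
  dics <- vapply(c("MoSTST", "MoNST", "MoSNSN", "MoNN"), function(lab) {
    cfg <- config_from_label(lab, fixed_covariates = c("Z1", "Z2"),
                             mcmc = mcmc_control(chains = 1, iter = 600,
                                                 burnin = 250, thin = 1, seed = 31))
    dic(run_mcmc(sim$data, cfg))$dic
  }, 0)
  expect_identical(names(which.max(dics)), "MoNN")
})

test_that("the marginal-errors deviance variant integrates the latents", {
  sim <- simulate_dataset(sim_design(m = 8), seed = 17)
  cfg <- model_config("skew_normal", "skew_normal",
                      fixed_covariates = c("Z1", "Z2"),
                      mcmc = mcmc_control(chains = 1, iter = 200, burnin = 80,
                                          thin = 1, seed = 3))
  b <- build_designs(sim$data, cfg)
  st <- initialize_state(b, cfg, seed = 4)
  st$delta_eps <- 1
  dev_m <- deviance_state(st, b, cfg, type = "marginal_errors")
  expect_true(is.finite(dev_m))
  # at zero skewness and unit mixing the two conventions coincide
  st0 <- st
  st0$delta_eps <- 0
  expect_equal(deviance_state(st0, b, cfg, type = "marginal_errors"),
               deviance_state(st0, b, cfg, type = "conditional"),
               tolerance = 1e-8)
})
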