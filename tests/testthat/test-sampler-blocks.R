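# Each Gibbs block is certified against a closed-form conditional oracle on
# a toy where the conditional is hand-derivable.  Uncentered configurations
# (center = FALSE) are used where the oracle assumes the raw location-0
# parametrization.

blk_cfg <- function(re = "normal", err = "normal", center = FALSE) {
  model_config(re, err, center = center, mcmc = mcmc_control(chains = 1))
}

extras <- function(state) attr(state, "extras")

test_that("fixed-effect conditional mean equals least squares under a flat prior", {
  set.seed(21)
  x <- rnorm(30)
  subj <- rep(1:6, each = 5)
  y <- 1 + 2 * x + rnorm(30, sd = 0.3)
  b <- manual_bundle(y, subj, cbind(`(Intercept)` = 1, x = x))
  cfg <- blk_cfg()
  st <- initialize_state(b, cfg, seed = 1)
  st$phi <- matrix(0, b$m, 1)
  pr <- default_priors(b, prior_spec(alpha_var = 1e10))
  up <- update_fixed_effects(st, b, cfg, pr)
  ols <- qr.solve(qr(b$Z), b$y)
  expect_equal(unname(extras(up)$cond_mean), unname(ols), tolerance = 1e-8)

  # prior domination: vanishing prior variance pins the draw at the prior mean
  pr0 <- default_priors(b, prior_spec(alpha_var = 1e-12))
  up0 <- update_fixed_effects(st, b, cfg, pr0)
  expect_lt(max(abs(extras(up0)$cond_mean)), 1e-6)
  expect_lt(max(abs(up0$alpha)), 1e-4)
})

test_that("fixed-effect draws match the analytic conditional moments", {
  set.seed(22)
  x <- rnorm(12)
  b <- manual_bundle(rnorm(12, 1 + x), rep(1:3, each = 4),
                     cbind(`(Intercept)` = 1, x = x))
  cfg <- blk_cfg()
  st <- initialize_state(b, cfg, seed = 2)
  st$phi <- matrix(0, b$m, 1)
  pr <- default_priors(b)
  ex <- extras(update_fixed_effects(st, b, cfg, pr))
  draws <- t(replicate(4000, update_fixed_effects(st, b, cfg, pr)$alpha))
  se <- sqrt(diag(ex$cond_cov) / 4000)
  expect_true(all(abs(colMeans(draws) - ex$cond_mean) < 4 * se))
  expect_equal(unname(apply(draws, 2, var)), unname(diag(ex$cond_cov)),
               tolerance = 0.1)
})

test_that("random-effect conditional matches the scalar conjugacy oracle", {
  set.seed(23)
  n <- 7
  y <- rnorm(n, mean = 3)
  b <- manual_bundle(y, rep(1, n), matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cfg <- blk_cfg()
  st <- initialize_state(b, cfg, seed = 3)
  st$alpha <- 1.2
  st$sigma2_eps <- 0.8
  tau2 <- 0.5
  st$Sigma_phi <- matrix(tau2)
  up <- update_random_effects(st, b, cfg)
  resid <- y - 1.2
  prec <- 1 / tau2 + n / 0.8
  expect_equal(as.numeric(extras(up)$cond_mean),
               sum(resid) / 0.8 / prec, tolerance = 1e-8)

  # infinite prior precision pins the random effect at zero
  st$Sigma_phi <- matrix(1e-12)
  up0 <- update_random_effects(st, b, cfg)
  expect_lt(abs(up0$phi[1, 1]), 1e-4)
})

test_that("a subject without visits draws its random effect from the prior", {
  b <- empty_bundle(m = 400, p = 1, d = 1)
  b$y <- numeric(0)
  cfg <- blk_cfg("skew_normal", "normal")
  st <- initialize_state(b, cfg, seed = 4)
  st$delta_phi <- 2
  st$W_phi <- matrix(1.5, 400, 1)
  st$Sigma_phi <- matrix(0.49)
  up <- update_random_effects(st, b, cfg)
  # prior N(delta * W, Sigma) since there is no likelihood term
  expect_equal(as.numeric(extras(up)$cond_mean), rep(3, 400), tolerance = 1e-8)
  expect_equal(mean(up$phi), 3, tolerance = 4 * 0.7 / sqrt(400))
  expect_equal(sd(up$phi), 0.7, tolerance = 0.1)
})

test_that("truncated-latent conditional reduces to the prior at zero skewness", {
  set.seed(24)
  n <- 10
  b <- manual_bundle(rnorm(n), rep(1:2, each = 5), matrix(1, n, 1))
  cfg <- blk_cfg("normal", "skew_normal")
  st <- initialize_state(b, cfg, seed = 5)
  st$phi <- matrix(0, 2, 1)
  st$delta_eps <- 0
  up <- update_truncated_latents(st, b, cfg)
  ex <- extras(up)
  expect_equal(unname(ex$weps_cond_mean), rep(0, n))
  expect_equal(unname(ex$weps_cond_sd), rep(1, n))
  draws <- replicate(600, update_truncated_latents(st, b, cfg)$W_eps)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), sqrt(2 / pi), tolerance = 4 * 0.6 / sqrt(600 * n))
})

test_that("one-visit truncated-latent conditional matches the univariate oracle", {
  y0 <- 4.2; a0 <- 1.0; d0 <- 2.0; s2 <- 0.5
  b <- manual_bundle(y0, 1, matrix(1, 1, 1))
  cfg <- blk_cfg("normal", "skew_normal")
  st <- initialize_state(b, cfg, seed = 6)
  st$alpha <- a0; st$phi <- matrix(0, 1, 1)
  st$delta_eps <- d0; st$sigma2_eps <- s2
  mu <- d0 * (y0 - a0) / (s2 + d0^2)
  sdv <- sqrt(s2 / (s2 + d0^2))
  up <- update_truncated_latents(st, b, cfg)
  expect_equal(as.numeric(extras(up)$weps_cond_mean), mu, tolerance = 1e-10)
  expect_equal(as.numeric(extras(up)$weps_cond_sd), sdv, tolerance = 1e-10)
  draws <- replicate(4000, update_truncated_latents(st, b, cfg)$W_eps[1])
  expect_equal(mean(draws), tnorm_pos_mean(mu, sdv),
               tolerance = 4 * sd(draws) / sqrt(4000))
})

test_that("error-variance conditional matches the inverse-gamma oracle", {
  set.seed(25)
  n <- 40
  y <- rnorm(n, 2, 1.5)
  b <- manual_bundle(y, rep(1:8, each = 5), matrix(1, n, 1))
  cfg <- blk_cfg()
  st <- initialize_state(b, cfg, seed = 7)
  st$alpha <- 2; st$phi <- matrix(0, 8, 1)
  pr <- default_priors(b, prior_spec(sigma2_shape = 2, sigma2_rate = 1))
  up <- update_scales(st, b, cfg, pr)
  ex <- extras(up)
  expect_equal(ex$sigma2_shape, 2 + n / 2)
  expect_equal(ex$sigma2_rate, 1 + sum((y - 2)^2) / 2)
  draws <- replicate(3000, update_scales(st, b, cfg, pr)$sigma2_eps)
  ig_mean <- ex$sigma2_rate / (ex$sigma2_shape - 1)
  expect_equal(mean(draws), ig_mean, tolerance = 4 * sd(draws) / sqrt(3000))

  # zero residuals with a vague prior: posterior collapses toward zero
  b0 <- manual_bundle(rep(2, 1000), rep(1:10, each = 100), matrix(1, 1000, 1))
  st0 <- initialize_state(b0, cfg, seed = 8)
  st0$alpha <- 2; st0$phi <- matrix(0, 10, 1)
  d0 <- replicate(200, update_scales(st0, b0, cfg)$sigma2_eps)
  expect_lt(mean(d0), 1e-3)
})

test_that("covariance conditional carries the inverse-Wishart scale and dof", {
  set.seed(26)
  sim <- simulate_dataset(sim_design(m = 12), seed = 3)
  cfg <- model_config("skew_normal", "normal", center = FALSE,
                      fixed_covariates = c("Z1", "Z2"))
  b <- build_designs(sim$data, cfg)
  st <- initialize_state(b, cfg, seed = 9)
  st$phi <- matrix(rnorm(12 * 4), 12, 4)
  st$W_phi <- matrix(abs(rnorm(12 * 4)) + 0.1, 12, 4)
  st$delta_phi <- c(1, -0.5, 0.2, 0)
  pr <- default_priors(b)
  up <- update_scales(st, b, cfg, pr)
  ex <- extras(up)
  S <- diag(0.01, 4)
  for (i in 1:12) {
    u <- st$phi[i, ] - st$delta_phi * st$W_phi[i, ]
    S <- S + u %*% t(u)
  }
  expect_equal(ex$wishart_df, 4 + 12)
  expect_equal(unname(ex$wishart_scale), unname(S), tolerance = 1e-10)
  ev <- eigen(up$Sigma_phi, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("skewness conditional is the prior when the latents vanish", {
  set.seed(27)
  n <- 20
  b <- manual_bundle(rnorm(n), rep(1:4, each = 5), matrix(1, n, 1))
  cfg <- blk_cfg("normal", "skew_normal")
  st <- initialize_state(b, cfg, seed = 10)
  st$phi <- matrix(0, 4, 1)
  st$W_eps <- rep(0, n)  # forced degenerate latents
  pr <- default_priors(b, prior_spec(kappa_delta_eps = 9))
  up <- update_skewness(st, b, cfg, pr)
  expect_equal(extras(up)$deps_mean, 0)
  expect_equal(extras(up)$deps_var, 9)
  draws <- replicate(1500, update_skewness(st, b, cfg, pr)$delta_eps)
  expect_equal(mean(draws), 0, tolerance = 4 * 3 / sqrt(1500))
  expect_equal(sd(draws), 3, tolerance = 0.25)

  # vanishing prior variance pins the skewness at zero
  pr0 <- default_priors(b, prior_spec(kappa_delta_eps = 1e-12))
  expect_lt(abs(update_skewness(st, b, cfg, pr0)$delta_eps), 1e-4)
})

test_that("skewness conditional recovers a generating delta of 3", {
  set.seed(28)
  n <- 400
  W <- abs(rnorm(n))
  y <- 1 + 3 * W + rnorm(n, sd = 0.5)
  b <- manual_bundle(y, rep(1:20, each = 20), matrix(1, n, 1))
  cfg <- blk_cfg("normal", "skew_normal")
  st <- initialize_state(b, cfg, seed = 11)
  st$alpha <- 1; st$phi <- matrix(0, 20, 1)
  st$W_eps <- W[order(rep(1:20, each = 20))]
  st$sigma2_eps <- 0.25
  up <- update_skewness(st, b, cfg)
  ex <- extras(up)
  expect_lt(abs(ex$deps_mean - 3), 3 * sqrt(ex$deps_var))
})

test_that("mixing conditional matches the gamma conjugacy oracle", {
  y <- c(1.3, 0.2, -0.5)
  b <- manual_bundle(y, rep(1, 3), matrix(1, 3, 1))
  cfg <- blk_cfg("skew_t", "skew_t")
  st <- initialize_state(b, cfg, seed = 12)
  st$alpha <- 0.5; st$phi <- matrix(0.3, 1, 1)
  st$W_eps <- c(0.4, 1.1, 0.9); st$W_phi <- matrix(0.7, 1, 1)
  st$delta_eps <- 1.2; st$delta_phi <- 0.8
  st$sigma2_eps <- 0.6; st$Sigma_phi <- matrix(0.5)
  st$rho_eps <- 6; st$rho_phi <- 8
  up <- update_mixing(st, b, cfg)
  ex <- extras(up)
  e <- y - 0.5 - 0.3 - 1.2 * st$W_eps
  expect_equal(ex$veps_shape[1], 6 / 2 + 3)
  expect_equal(ex$veps_rate[1],
               6 / 2 + sum(e^2) / (2 * 0.6) + sum(st$W_eps^2) / 2,
               tolerance = 1e-12)
  u <- 0.3 - 0.8 * 0.7
  expect_equal(ex$vphi_shape[1], 8 / 2 + 1)
  expect_equal(ex$vphi_rate[1], 8 / 2 + u^2 / (2 * 0.5) + 0.7^2 / 2,
               tolerance = 1e-12)
  draws <- replicate(3000, {
    s <- update_mixing(st, b, cfg)
    c(s$v_eps[1], s$v_phi[1])
  })
  expect_true(all(draws > 0))
  expect_equal(mean(draws[1, ]), ex$veps_shape[1] / ex$veps_rate[1],
               tolerance = 4 * sd(draws[1, ]) / sqrt(3000))
  expect_equal(mean(draws[2, ]), ex$vphi_shape[1] / ex$vphi_rate[1],
               tolerance = 4 * sd(draws[2, ]) / sqrt(3000))
})

test_that("dof sampler concentrates at the likelihood-grid optimum", {
  set.seed(29)
  m <- 2000
  v <- rgamma(m, 4, rate = 4)  # generating dof 8
  b <- empty_bundle(m = m, p = 1, d = 1)
  cfg <- blk_cfg("skew_t", "skew_t")
  st <- initialize_state(b, cfg, seed = 13)
  st$v_eps <- v
  rho_grid <- seq(3.05, 20, by = 0.01)
  lp <- vapply(rho_grid, function(r) {
    h <- r / 2
    m * (h * log(h) - lgamma(h)) + h * sum(log(v)) - h * sum(v) -
      0.5 * r + log(r - 3)
  }, 0)
  map <- rho_grid[which.max(lp)]
  expect_lt(abs(map - 8), 1)
  chain <- numeric(3000)
  for (i in seq_len(3000)) {
    st <- update_dof(st, b, cfg, step = 0.3)
    chain[i] <- st$rho_eps
  }
  expect_true(all(chain > 3))
  expect_lt(abs(mean(chain[-(1:500)]) - map), 1)
  acc <- extras(st)$acc_eps
  expect_true(acc >= 0 && acc <= 1)
})

test_that("every block preserves the latent-state invariants", {
  sim <- simulate_dataset(sim_design(m = 15), seed = 6)
  cfg <- model_config("skew_t", "skew_t", fixed_covariates = c("Z1", "Z2"))
  b <- build_designs(sim$data, cfg)
  st <- initialize_state(b, cfg, seed = 14)
  expect_true(validate_state(st, cfg))
  for (fn in list(update_fixed_effects, update_random_effects,
                  update_truncated_latents, update_scales,
                  update_skewness, update_mixing)) {
    st <- fn(st, b, cfg)
    expect_true(validate_state(st, cfg))
  }
  st <- update_dof(st, b, cfg)
  expect_true(validate_state(st, cfg))
})

test_that("initialization is deterministic, errors on collinearity, and is exact on noiseless data", {
  sim <- simulate_dataset(sim_design(m = 10), seed = 8)
  cfg <- model_config("skew_t", "skew_t", fixed_covariates = c("Z1", "Z2"))
  b <- build_designs(sim$data, cfg)
  s1 <- initialize_state(b, cfg, seed = 1)
  s2 <- initialize_state(b, cfg, seed = 2)
  expect_identical(s1$alpha, s2$alpha)        # deterministic part
  expect_false(identical(s1$delta_eps, s2$delta_eps))  # jitter differs

  b2 <- b
  b2$Z <- cbind(b$Z, dup = b$Z[, 2])
  b2$p <- ncol(b2$Z)
  b2$z_names <- colnames(b2$Z)
  expect_error(initialize_state(b2, cfg), "collinear.*dup")

  # noiseless linear data: initial alpha reproduces the coefficients
  set.seed(30)
  x <- rnorm(40)
  bl <- manual_bundle(2 + 3 * x, rep(1:8, each = 5),
                      cbind(`(Intercept)` = 1, x = x))
  s <- initialize_state(bl, blk_cfg(), seed = 3)
  expect_equal(unname(s$alpha), c(2, 3), tolerance = 1e-6)
})
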