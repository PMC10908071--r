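# R-side surface of the Metropolis-within-Gibbs sampler.  All numerical work
# happens in src/sampler.cpp; these wrappers assemble inputs, name draws, and
# expose each Gibbs block individually so its full conditional can be checked
# against closed-form oracles.

sampler_inputs <- function(bundle, config, priors = NULL) {
  stopifnot(inherits(bundle, "design_bundle"), inherits(config, "model_config"))
  list(
    dat = list(y = bundle$y, Z = unname(bundle$Z), R = unname(bundle$R),
               start = bundle$start, len = bundle$len),
    pri = if (is.null(priors)) {
      default_priors(bundle, config$priors)
    } else if (inherits(priors, "prior_spec")) {
      default_priors(bundle, priors)
    } else {
      priors  # already expanded against this bundle
    },
    cfg = list(re_fl = flavor_code(config$re_flavor),
               err_fl = flavor_code(config$err_flavor),
               center = config$center)
  )
}

#' Parameter names of the retained draws
#'
#' @param bundle a [build_designs()] bundle.
#' @return character vector naming every column the sampler records.
#' @keywords internal
param_names <- function(bundle) {
  d <- bundle$d
  sig <- character(0)
  for (j in seq_len(d)) for (i in seq_len(j)) {
    sig <- c(sig, sprintf("Sigma_phi[%d,%d]", i, j))
  }
  c(paste0("alpha[", bundle$z_names, "]"), "sigma2_eps", sig,
    paste0("delta_phi[", seq_len(d), "]"), "delta_eps",
    "rho_phi", "rho_eps", "deviance")
}

# columns meaningful under the configured flavors (others are pinned)
active_params <- function(bundle, config) {
  nm <- param_names(bundle)
  drop <- character(0)
  if (config$re_flavor == "normal") drop <- c(drop, grep("^delta_phi", nm, value = TRUE))
  if (config$err_flavor == "normal") drop <- c(drop, "delta_eps")
  if (config$re_flavor != "skew_t") drop <- c(drop, "rho_phi")
  if (config$err_flavor != "skew_t") drop <- c(drop, "rho_eps")
  setdiff(nm, drop)
}

#' Initialize the latent state
#'
#' Deterministic moment-based initialization: fixed effects from least
#' squares on the stacked fixed design (after a rank check that names any
#' collinear columns), residual variance for the error scale, identity
#' random-effect covariance, zero random effects, unit latents and mixing
#' variables, degrees of freedom at 5, and skewness at 0 plus a small seeded
#' jitter.
#'
#' @param bundle a [build_designs()] bundle.
#' @param config a [model_config()].
#' @param seed optional integer seed for the jitter.
#' @return a named list, the full latent-state configuration.
#' @export
initialize_state <- function(bundle, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- bundle$Z
  if (nrow(Z) == 0L) {
    # prior-only run: nothing to regress on
    alpha <- rep(0, ncol(Z))
    sigma2 <- 1
  } else {
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
      stop("initialize_state: stacked fixed design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    alpha <- qr.coef(qrz, bundle$y)
    resid <- bundle$y - Z %*% alpha
    sigma2 <- max(stats::var(as.numeric(resid)), 1e-8)
  }
  d <- bundle$d
  jit <- function(k, on) if (on) stats::rnorm(k, 0, 0.01) else rep(0, k)
  list(
    alpha = as.numeric(alpha),
    phi = matrix(0, bundle$m, d),
    W_phi = matrix(1, bundle$m, d),
    W_eps = rep(1, bundle$n),
    v_phi = rep(1, bundle$m),
    v_eps = rep(1, bundle$m),
    sigma2_eps = sigma2,
    Sigma_phi = diag(d),
    delta_phi = jit(d, config$re_flavor != "normal"),
    delta_eps = jit(1, config$err_flavor != "normal"),
    rho_phi = if (config$re_flavor == "skew_t") 5 else Inf,
    rho_eps = if (config$err_flavor == "skew_t") 5 else Inf
  )
}

#' Check latent-state invariants
#'
#' Verifies positivity of the truncated latents and mixing variables,
#' positive definiteness of the covariance blocks, the dof truncation, and
#' that components pinned by the flavor sit at their degenerate values.
#'
#' @param state a latent state list.
#' @param config a [model_config()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_state <- function(state, config) {
  stopifnot(all(state$W_phi > 0), all(state$W_eps > 0),
            all(state$v_phi > 0), all(state$v_eps > 0),
            state$sigma2_eps > 0)
  ev <- eigen(state$Sigma_phi, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(min(ev) > 0)
  if (config$re_flavor == "normal") stopifnot(all(state$delta_phi == 0))
  if (config$err_flavor == "normal") stopifnot(state$delta_eps == 0)
  if (config$re_flavor == "skew_t") stopifnot(state$rho_phi > 3)
  if (config$err_flavor == "skew_t") stopifnot(state$rho_eps > 3)
  if (config$re_flavor != "skew_t") stopifnot(all(state$v_phi == 1))
  if (config$err_flavor != "skew_t") stopifnot(all(state$v_eps == 1))
  invisible(TRUE)
}

run_block <- function(block, state, bundle, config, priors = NULL, step = 0.3) {
  inp <- sampler_inputs(bundle, config, priors)
  out <- cpp_update_block(block, state, inp$dat, inp$pri, inp$cfg, step)
  st <- out$state
  # Armadillo vectors come back as n-by-1 matrices; restore R-side shapes
  for (f in c("alpha", "W_eps", "v_phi", "v_eps", "delta_phi")) {
    st[[f]] <- as.numeric(st[[f]])
  }
  for (f in c("phi", "W_phi", "Sigma_phi")) st[[f]] <- as.matrix(st[[f]])
  ex <- lapply(out$extras, function(x) {
    if (is.matrix(x) && ncol(x) == 1L && block != 2L) as.numeric(x) else x
  })
  if (block == 4L && !is.null(ex$wishart_scale)) {
    ex$wishart_scale <- as.matrix(out$extras$wishart_scale)
  }
  if (block == 5L && !is.null(ex$dphi_cov)) {
    ex$dphi_cov <- as.matrix(out$extras$dphi_cov)
  }
  attr(st, "extras") <- ex
  st
}

#' Gibbs update of the fixed effects
#'
#' Conjugate multivariate-normal draw of the fixed-effect vector given the
#' centered residuals, per-subject precision weights and its normal prior.
#' The conditional mean and covariance are attached as attribute `"extras"`.
#'
#' @param state latent state list.
#' @param bundle design bundle.
#' @param config model configuration.
#' @param priors expanded prior list (defaults resolved from the bundle).
#' @return updated state.
#' @export
update_fixed_effects <- function(state, bundle, config, priors = NULL) {
  run_block(1L, state, bundle, config, priors)
}

#' Gibbs update of the per-subject random effects
#'
#' Conjugate multivariate-normal draw of each subject's random-effect vector
#' given its likelihood contribution and the skew prior mean; subjects
#' without visits receive prior draws.
#'
#' @inheritParams update_fixed_effects
#' @return updated state.
#' @export
update_random_effects <- function(state, bundle, config, priors = NULL) {
  run_block(2L, state, bundle, config, priors)
}

#' Gibbs update of the positive truncated latents
#'
#' Componentwise positive-truncated-normal draws of the per-visit error
#' latents and the per-subject random-effect latents; each coordinate enters
#' the likelihood linearly through the skewness parameter.
#'
#' @inheritParams update_fixed_effects
#' @return updated state.
#' @export
update_truncated_latents <- function(state, bundle, config, priors = NULL) {
  run_block(3L, state, bundle, config, priors)
}

#' Gibbs update of the scale parameters
#'
#' Inverse-gamma draw of the error variance and inverse-Wishart draw of the
#' random-effect covariance from their conjugate full conditionals.
#'
#' @inheritParams update_fixed_effects
#' @return updated state.
#' @export
update_scales <- function(state, bundle, config, priors = NULL) {
  run_block(4L, state, bundle, config, priors)
}

#' Gibbs update of the skewness parameters
#'
#' Conjugate normal draws of the error and random-effect skewness
#' parameters, treating the truncated latents as known regressors.
#'
#' @inheritParams update_fixed_effects
#' @return updated state.
#' @export
update_skewness <- function(state, bundle, config, priors = NULL) {
  run_block(5L, state, bundle, config, priors)
}

#' Gibbs update of the gamma mixing variables
#'
#' Per-subject conjugate gamma draws of the scale-mixture variables of the
#' skew-t flavors (skipped, pinned at 1, otherwise).
#'
#' @inheritParams update_fixed_effects
#' @return updated state.
#' @export
update_mixing <- function(state, bundle, config, priors = NULL) {
  run_block(6L, state, bundle, config, priors)
}

#' Metropolis-Hastings update of the degrees of freedom
#'
#' Random-walk proposal on log(rho - 3) against the gamma-mixing likelihood
#' and truncated-exponential prior (plus the centering terms when the
#' centered parametrization is on); acceptance probabilities are attached as
#' attribute `"extras"`.
#'
#' @inheritParams update_fixed_effects
#' @param step random-walk standard deviation on the log scale.
#' @return updated state.
#' @export
update_dof <- function(state, bundle, config, priors = NULL, step = 0.3) {
  run_block(7L, state, bundle, config, priors, step)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Executes the fixed update cycle (fixed effects, random effects, truncated
#' latents, scales, skewness, mixing, degrees of freedom) over independently
#' seeded chains and returns thinned post-burn-in draws.  Deterministic given
#' the master seed.
#'
#' @param data a [longitudinal_data()] or a prebuilt [build_designs()]
#'   bundle.
#' @param config a [model_config()].
#' @param mcmc an [mcmc_control()]; defaults to `config$mcmc`.
#' @param priors optional [prior_spec()] overriding `config$priors`.
#' @param chain_seeds optional integer vector overriding the per-chain seeds
#'   derived from the master seed (chains are exchangeable: permuting these
#'   permutes the returned chains).
#' @return an object of class `"splmm_chains"`: per-chain draw matrices with
#'   stable parameter names, posterior means of the latent nodes, acceptance
#'   rates for the Metropolis blocks, and run metadata.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_design(m = 40), seed = 1)
#' cfg <- model_config("normal", "normal",
#'                     mcmc = mcmc_control(chains = 2, iter = 600, burnin = 200))
#' fit <- run_mcmc(sim$data, cfg)
#' posterior_summary(fit)
#' }
#' @export
run_mcmc <- function(data, config, mcmc = NULL, priors = NULL,
                     chain_seeds = NULL) {
  stopifnot(inherits(config, "model_config"))
  bundle <- if (inherits(data, "design_bundle")) data else build_designs(data, config)
  mcmc <- mcmc %||% config$mcmc
  stopifnot(inherits(mcmc, "mcmc_control"))
  inp <- sampler_inputs(bundle, config, priors)
  if (is.null(chain_seeds)) {
    set.seed(mcmc$seed)
    chain_seeds <- sample.int(.Machine$integer.max - 1L, mcmc$chains)
  }
  stopifnot(length(chain_seeds) == mcmc$chains)
  nm <- param_names(bundle)
  keep <- active_params(bundle, config)
  draws <- vector("list", mcmc$chains)
  latents <- vector("list", mcmc$chains)
  acc <- matrix(NA_real_, mcmc$chains, 2,
                dimnames = list(NULL, c("rho_eps", "rho_phi")))
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(mcmc$chains)) {
    set.seed(chain_seeds[ch])
    init <- initialize_state(bundle, config)
    res <- tryCatch(
      cpp_run_chain(inp$dat, inp$pri, inp$cfg, init, mcmc$iter, mcmc$burnin,
                    mcmc$thin, mcmc$step, mcmc$target_acc),
      error = function(e) stop("run_mcmc: chain ", ch, " failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    dm <- res$draws
    colnames(dm) <- nm
    draws[[ch]] <- dm[, keep, drop = FALSE]
    latents[[ch]] <- res[c("phi_mean", "W_phi_mean", "W_eps_mean",
                           "v_eps_mean", "v_phi_mean")]
    acc[ch, ] <- c(res$acc_rho_eps, res$acc_rho_phi)
  }
  structure(list(
    draws = draws, params = keep, latents = latents, acceptance = acc,
    bundle = bundle, config = config, priors = inp$pri,
    label = model_label(config),
    meta = list(seed = mcmc$seed, chain_seeds = chain_seeds,
                iter = mcmc$iter, burnin = mcmc$burnin, thin = mcmc$thin,
                retained_per_chain = (mcmc$iter - mcmc$burnin) %/% mcmc$thin,
                elapsed = proc.time()[["elapsed"]] - t0)
  ), class = "splmm_chains")
}

#' Pooled draws as a matrix
#'
#' @param x an `splmm_chains` object.
#' @param ... unused.
#' @return matrix of pooled post-burn-in draws (rows = draws across chains).
#' @export
as.matrix.splmm_chains <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Posterior means of the latent nodes, averaged over chains
#' @keywords internal
latent_means <- function(chains) {
  nms <- names(chains$latents[[1]])
  out <- lapply(nms, function(nm) {
    Reduce(`+`, lapply(chains$latents, `[[`, nm)) / length(chains$latents)
  })
  names(out) <- nms
  out
}

#' @export
print.splmm_chains <- function(x, ...) {
  cat(sprintf("%s fit: %d chain(s) x %d retained draws (%d iter, burn-in %d, thin %d)\n",
              x$label, length(x$draws), nrow(x$draws[[1]]),
              x$meta$iter, x$meta$burnin, x$meta$thin))
  if (any(is.finite(x$acceptance))) {
    a <- colMeans(x$acceptance)
    cat("  MH acceptance:",
        paste(names(a)[is.finite(a)],
              sprintf("%.2f", a[is.finite(a)]), collapse = ", "), "\n")
  }
  cat(sprintf("  elapsed: %.1f s\n", x$meta$elapsed))
  invisible(x)
}

#' @export
summary.splmm_chains <- function(object, ...) {
  posterior_summary(object, ...)
}
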