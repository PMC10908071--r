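#' MCMC control settings
#'
#' @param chains number of independent chains.
#' @param iter iterations per chain.
#' @param burnin burn-in iterations discarded from each chain.
#' @param thin thinning interval for retained draws.
#' @param seed integer master seed; per-chain seeds are derived from it.
#' @param step initial random-walk step for the degrees-of-freedom
#'   Metropolis-Hastings block on log(rho - 3); Robbins-Monro adapted during
#'   burn-in toward acceptance `target_acc`, then held fixed.
#' @param target_acc Metropolis-Hastings target acceptance rate.
#' @return a list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 3L, iter = 8000L, burnin = 3000L,
                         thin = 5L, seed = 1L, step = 0.3,
                         target_acc = 0.35) {
  stopifnot(chains >= 1L, iter > burnin, burnin >= 0L, thin >= 1L, step > 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), step = step,
                 target_acc = target_acc),
            class = "mcmc_control")
}

flavor_code <- function(flavor) {
  switch(flavor, normal = 0L, skew_normal = 1L, skew_t = 2L,
         stop("unknown flavor: ", flavor))
}

flavor_short <- function(flavor) {
  switch(flavor, normal = "N", skew_normal = "SN", skew_t = "ST")
}

#' Model configuration
#'
#' Assembles the distributional flavors, spline specification, covariates and
#' MCMC settings of a semiparametric partially linear mixed-effects model
#' (SPPLMEM), or of the fully parametric linear model (FPLMEM) when
#' `linear_time = TRUE`.
#'
#' The four flavor pairs studied throughout the package are named
#' MoSTST (skew-t random effects and errors), MoNST (normal random effects,
#' skew-t errors), MoSNSN (skew-normal both) and MoNN (normal both, the
#' conventional Gaussian mixed model).
#'
#' @param re_flavor,err_flavor distribution of the random effects / errors:
#'   `"normal"`, `"skew_normal"` or `"skew_t"`.
#' @param spline a [spline_spec()] for the time effect (SPPLMEM).
#' @param linear_time if `TRUE`, fit the fully parametric model with a linear
#'   time effect and random intercept + slope instead of the spline block.
#' @param fixed_covariates names of covariate columns entering the fixed
#'   design.
#' @param center center the skew latent terms by their prior mean so that the
#'   location parameters coincide with the marginal means (default `TRUE`);
#'   with `FALSE` the raw location-0 parametrization is sampled.
#' @param min_visits minimum visits per subject when building designs.
#' @param priors optional [prior_spec()]; defaults are resolved from the
#'   design dimension by [default_priors()].
#' @param mcmc an [mcmc_control()].
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(re_flavor = c("skew_t", "normal", "skew_normal"),
                         err_flavor = c("skew_t", "normal", "skew_normal"),
                         spline = spline_spec(),
                         linear_time = FALSE,
                         fixed_covariates = character(),
                         center = TRUE,
                         min_visits = 3L,
                         priors = NULL,
                         mcmc = mcmc_control()) {
  re_flavor <- match.arg(re_flavor)
  err_flavor <- match.arg(err_flavor)
  stopifnot(inherits(spline, "spline_spec") || isTRUE(linear_time))
  structure(list(re_flavor = re_flavor, err_flavor = err_flavor,
                 spline = spline, linear_time = isTRUE(linear_time),
                 fixed_covariates = as.character(fixed_covariates),
                 center = isTRUE(center),
                 min_visits = as.integer(min_visits),
                 priors = priors, mcmc = mcmc),
            class = "model_config")
}

#' Model label from flavor pair
#'
#' Maps the (random-effect, error) flavor pair to the standard model name:
#' `(skew_t, skew_t)` = MoSTST, `(normal, skew_t)` = MoNST,
#' `(skew_normal, skew_normal)` = MoSNSN, `(normal, normal)` = MoNN (or
#' FPLMEM when the time effect is linear).  Other pairs get a composite
#' `Mo<re><err>` label.
#'
#' @param config a [model_config()].
#' @return character label.
#' @export
model_label <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$linear_time && config$re_flavor == "normal" &&
      config$err_flavor == "normal") {
    return("FPLMEM")
  }
  paste0("Mo", flavor_short(config$re_flavor), flavor_short(config$err_flavor))
}

#' Model configuration from a label
#'
#' Inverse of [model_label()] over the five named models.
#'
#' @param label one of `"MoSTST"`, `"MoNST"`, `"MoSNSN"`, `"MoNN"`,
#'   `"FPLMEM"`.
#' @param ... further arguments passed to [model_config()].
#' @return a [model_config()].
#' @export
config_from_label <- function(label, ...) {
  flv <- switch(label,
    MoSTST = c("skew_t", "skew_t"),
    MoNST = c("normal", "skew_t"),
    MoSNSN = c("skew_normal", "skew_normal"),
    MoNN = c("normal", "normal"),
    FPLMEM = c("normal", "normal"),
    stop("unknown model label: ", label)
  )
  model_config(re_flavor = flv[1], err_flavor = flv[2],
               linear_time = identical(label, "FPLMEM"), ...)
}

#' Prior hyperparameters
#'
#' Weakly informative priors of the hierarchical model: independent normals
#' for the fixed effects and skewness parameters, inverse-Wishart for the
#' random-effect covariance, inverse-gamma for the error variance, and
#' exponential priors truncated to (3, Inf) for the skew-t degrees of
#' freedom.
#'
#' @param alpha_mean,alpha_var prior mean vector and (diagonal) variance
#'   vector for the fixed effects; scalars are recycled at design-build time.
#' @param kappa_delta_phi,kappa_delta_eps prior variances of the skewness
#'   parameters.
#' @param D_phi,nu_phi inverse-Wishart scale matrix (scalar = multiple of the
#'   identity) and degrees of freedom.
#' @param sigma2_shape,sigma2_rate inverse-gamma shape and rate for the error
#'   variance.
#' @param rho_rate_phi,rho_rate_eps exponential rates for the dof priors.
#' @param rho_trunc lower truncation of the dof priors.
#' @return a list of class `"prior_spec"`.
#' @export
prior_spec <- function(alpha_mean = 0, alpha_var = 100,
                       kappa_delta_phi = 100, kappa_delta_eps = 100,
                       D_phi = 0.01, nu_phi = NULL,
                       sigma2_shape = 0.01, sigma2_rate = 0.01,
                       rho_rate_phi = 0.5, rho_rate_eps = 0.5,
                       rho_trunc = 3) {
  stopifnot(all(alpha_var > 0), all(kappa_delta_phi > 0), kappa_delta_eps > 0,
            sigma2_shape > 0, sigma2_rate > 0,
            rho_rate_phi > 0, rho_rate_eps > 0)
  structure(list(alpha_mean = alpha_mean, alpha_var = alpha_var,
                 kappa_delta_phi = kappa_delta_phi,
                 kappa_delta_eps = kappa_delta_eps,
                 D_phi = D_phi, nu_phi = nu_phi,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 rho_rate_phi = rho_rate_phi, rho_rate_eps = rho_rate_eps,
                 rho_trunc = rho_trunc),
            class = "prior_spec")
}

#' Default priors resolved against a design
#'
#' Expands a [prior_spec()] to the dimensions of a design bundle: N(0, 100)
#' for every fixed-effect and skewness component, inverse-Wishart
#' IW(0.01 I_d, d) for the random-effect covariance, IG(0.01, 0.01) for the
#' error variance, and Exp(0.5) truncated above 3 for both degrees of
#' freedom.
#'
#' @param bundle a [build_designs()] bundle (used for dimensions).
#' @param priors optional partially specified [prior_spec()] to expand.
#' @return a fully expanded prior list.
#' @export
default_priors <- function(bundle, priors = NULL) {
  p <- bundle$p
  d <- bundle$d
  pr <- priors %||% prior_spec()
  stopifnot(inherits(pr, "prior_spec"))
  nu <- pr$nu_phi %||% d
  if (nu < d) stop("default_priors: inverse-Wishart dof must be >= dimension of phi")
  D <- pr$D_phi
  if (length(D) == 1L) D <- diag(as.numeric(D), d)
  D <- as.matrix(D)
  stopifnot(nrow(D) == d, ncol(D) == d, all(diag(D) > 0))
  list(alpha_mean = rep_len(pr$alpha_mean, p),
       alpha_var = rep_len(pr$alpha_var, p),
       kappa_delta_phi = rep_len(pr$kappa_delta_phi, d),
       kappa_delta_eps = pr$kappa_delta_eps,
       D_phi = D, nu_phi = nu,
       sigma2_shape = pr$sigma2_shape, sigma2_rate = pr$sigma2_rate,
       rho_rate_phi = pr$rho_rate_phi, rho_rate_eps = pr$rho_rate_eps,
       rho_trunc = pr$rho_trunc)
}

#' Build fixed and random design matrices
#'
#' Assembles the stacked designs of the reformulated model
#' \eqn{y_i = Z_i \alpha + R_i \varphi_i + \varepsilon_i}: for the SPPLMEM,
#' \eqn{Z_i = [1, \mathrm{covariates}, \mathrm{spline\ bases}]} and
#' \eqn{R_i = [1, \mathrm{spline\ bases}]} (random intercept plus random
#' spline coefficients); for the FPLMEM, \eqn{Z_i = [1, \mathrm{covariates},
#' t]} and \eqn{R_i = [1, t]}.  The same resolved spline knots feed both
#' blocks.
#'
#' @param data a [longitudinal_data()] object (re-filtered at
#'   `config$min_visits` if needed).
#' @param config a [model_config()].
#' @return an object of class `"design_bundle"`: stacked `y`, `Z`, `R`,
#'   0-based subject row offsets, visit counts and naming metadata.
#' @export
build_designs <- function(data, config) {
  stopifnot(inherits(data, "longitudinal_data"), inherits(config, "model_config"))
  covs <- config$fixed_covariates
  missing_cols <- setdiff(covs, names(data))
  if (length(missing_cols)) {
    stop("build_designs: covariates not in data: ", paste(missing_cols, collapse = ", "))
  }
  if (attr(data, "min_visits") < config$min_visits) {
    data <- longitudinal_data(as.data.frame(data), covariates = attr(data, "covariates"),
                              min_visits = config$min_visits)
  }
  df <- as.data.frame(data)
  X <- if (length(covs)) as.matrix(df[, covs, drop = FALSE]) else NULL

  if (config$linear_time) {
    Z <- cbind(`(Intercept)` = 1, X, time = df$time)
    R <- cbind(`(Intercept)` = 1, time = df$time)
    spline_resolved <- NULL
  } else {
    B <- natural_cubic_basis(df$time, config$spline)
    Z <- cbind(`(Intercept)` = 1, X, B)
    R <- cbind(`(Intercept)` = 1, B)
    spline_resolved <- spline_spec(
      interior_knots = attr(B, "interior_knots"),
      boundary_knots = attr(B, "boundary_knots"),
      include_intercept = config$spline$include_intercept
    )
  }
  subj <- df$subject
  len <- as.integer(table(subj))
  start <- c(0L, cumsum(len)[-length(len)])
  structure(list(
    y = df$response, Z = Z, R = R,
    start = start, len = len,
    m = nlevels(subj), n = nrow(df), p = ncol(Z), d = ncol(R),
    subjects = levels(subj),
    z_names = colnames(Z), r_names = colnames(R),
    spline = spline_resolved, linear_time = config$linear_time,
    covariates = covs
  ), class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat(sprintf("Design bundle: %d rows, %d subjects; Z %d col(s), R %d col(s)\n",
              x$n, x$m, x$p, x$d))
  cat("  fixed:", paste(x$z_names, collapse = ", "), "\n")
  cat("  random:", paste(x$r_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model %s: random effects %s, errors %s, %s time effect\n",
              model_label(x), x$re_flavor, x$err_flavor,
              if (x$linear_time) "linear" else "natural cubic spline"))
  invisible(x)
}
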