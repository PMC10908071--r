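#' Skew family specification
#'
#' Describes the distribution assigned to random effects or errors: normal,
#' skew-normal or skew-t, in the location-0 parametrization built from the
#' stochastic representation
#' \deqn{x = \delta \circ W + v^{-1/2} \, \mathrm{chol}(\Sigma)' z,}
#' where the coordinates of \eqn{W} are independent positive-truncated
#' \eqn{N(0, v^{-1})} latents, \eqn{v \sim \Gamma(\rho/2, \rho/2)} mixing
#' (pinned at 1 for the skew-normal and normal flavors), and \eqn{z} is
#' standard normal.  Location 0 is the parametrization location, not the
#' mean: for nonzero skewness the mean is \eqn{\delta E[v^{-1/2}]\sqrt{2/\pi}}.
#'
#' @param flavor one of `"normal"`, `"skew_normal"`, `"skew_t"`.
#' @param scale positive-definite scale matrix (or a positive scalar for a
#'   univariate family).
#' @param skewness skewness vector `delta` (scalar for univariate); must be 0
#'   (or omitted) for the normal flavor.
#' @param dof degrees of freedom, required for `"skew_t"` and must exceed 3
#'   (the prior truncation used throughout the package).
#' @return an object of class `"skew_family"`.
#' @export
skew_family <- function(flavor = c("normal", "skew_normal", "skew_t"),
                        scale = 1, skewness = 0, dof = NULL) {
  flavor <- match.arg(flavor)
  scale <- as.matrix(scale)
  d <- nrow(scale)
  if (ncol(scale) != d) stop("skew_family: 'scale' must be square")
  if (max(abs(scale - t(scale))) > 1e-10) stop("skew_family: 'scale' must be symmetric")
  ev <- eigen(scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("skew_family: 'scale' must be positive definite")
  skewness <- rep_len(as.numeric(skewness), d)
  if (flavor == "normal" && any(skewness != 0)) {
    stop("skew_family: normal flavor requires zero skewness")
  }
  if (flavor == "skew_t") {
    if (is.null(dof) || !is.finite(dof) || dof <= 3) {
      stop("skew_family: skew_t requires dof > 3")
    }
  } else {
    dof <- NULL
  }
  structure(list(flavor = flavor, scale = scale, skewness = skewness,
                 dof = dof, dim = d),
            class = "skew_family")
}

#' Positive-truncated normal draws
#'
#' Samples from \eqn{N(\mathrm{mean}, \mathrm{variance})} conditioned on the
#' positive half-line.  Numerically stable for means far below zero
#' (exponential-rejection sampling in the tail), which the Gibbs sampler
#' relies on.
#'
#' @param n number of draws.
#' @param mean,variance scalar or vector (recycled) truncated-normal
#'   parameters; `variance` must be positive.
#' @param seed optional integer seed set before drawing.
#' @return numeric vector of `n` strictly positive draws.
#' @export
rtnorm_pos <- function(n, mean = 0, variance = 1, seed = NULL) {
  if (any(variance <= 0)) stop("rtnorm_pos: 'variance' must be positive")
  if (!is.null(seed)) set.seed(seed)
  cpp_rtnorm_pos(as.integer(n), as.numeric(mean), sqrt(as.numeric(variance)))
}

#' Sample from a skew family
#'
#' Draws from the stochastic representation underlying the hierarchical
#' model: gamma mixing variable per draw (skew-t only), positive
#' truncated-normal latent vector, then correlated Gaussian noise.
#'
#' @param family a [skew_family()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return an `n` by `dim` matrix of draws.
#' @export
sample_skew <- function(family, n, seed = NULL) {
  stopifnot(inherits(family, "skew_family"))
  if (!is.null(seed)) set.seed(seed)
  d <- family$dim
  v <- if (family$flavor == "skew_t") {
    stats::rgamma(n, shape = family$dof / 2, rate = family$dof / 2)
  } else {
    rep(1, n)
  }
  # W | v ~ N(0, I/v) truncated > 0 -> v^{-1/2} |z| coordinatewise
  W <- matrix(abs(stats::rnorm(n * d)), n, d) / sqrt(v)
  Lz <- matrix(stats::rnorm(n * d), n, d) %*% chol(family$scale)
  sweep(W, 2, family$skewness, `*`) + Lz / sqrt(v)
}

#' Univariate skew log-density
#'
#' Log-density of the univariate skew-normal or skew-t implied by the
#' stochastic representation, with the latent variables integrated out
#' analytically: a 2 * density * CDF skewing form, Gaussian for the
#' skew-normal and Student-t for the skew-t.
#'
#' @param x numeric vector of evaluation points.
#' @param family a univariate [skew_family()].
#' @return numeric vector of log-density values.
#' @export
skew_logpdf_1d <- function(x, family) {
  stopifnot(inherits(family, "skew_family"))
  if (family$dim != 1L) stop("skew_logpdf_1d: family must be univariate")
  s2 <- family$scale[1, 1]
  del <- family$skewness[1]
  om2 <- s2 + del^2
  om <- sqrt(om2)
  z <- x / om
  if (family$flavor == "skew_t") {
    rho <- family$dof
    # X = v^{-1/2} S with S skew-normal: Azzalini-type skew-t density
    lt <- stats::dt(z, df = rho, log = TRUE) - log(om)
    u <- (del / sqrt(s2)) * z * sqrt((rho + 1) / (rho + z^2))
    lt + log(2) + stats::pt(u, df = rho + 1, log.p = TRUE)
  } else if (family$flavor == "skew_normal") {
    stats::dnorm(x, sd = om, log = TRUE) + log(2) +
      stats::pnorm(del * x / (sqrt(s2) * om), log.p = TRUE)
  } else {
    stats::dnorm(x, sd = sqrt(s2), log = TRUE)
  }
}

# mean of a positive-truncated N(0, 1/v) coordinate under v ~ Gamma(rho/2, rho/2),
# i.e. sqrt(2/pi) * E[v^{-1/2}]; the centering constant of the sampler
skew_latent_mean <- function(flavor, rho = NULL) {
  switch(flavor,
    normal = 0,
    skew_normal = sqrt(2 / pi),
    skew_t = sqrt(2 / pi) * sqrt(rho / 2) *
      exp(lgamma((rho - 1) / 2) - lgamma(rho / 2))
  )
}

#' @export
print.skew_family <- function(x, ...) {
  cat(sprintf("%s family, dim %d\n", x$flavor, x$dim))
  if (x$dim == 1L) {
    cat("  scale:", x$scale[1, 1], " skewness:", x$skewness, "\n")
  } else {
    cat("  skewness:", paste(signif(x$skewness, 4), collapse = ", "), "\n")
  }
  if (!is.null(x$dof)) cat("  dof:", x$dof, "\n")
  invisible(x)
}
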