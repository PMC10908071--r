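# Independent oracles and small fixture builders used across the suite.

# Truncated-power construction of the natural cubic spline space on the full
# knot sequence (boundary + interior).  Returns the M-dimensional basis
# including the constant; only the spanned space is comparable with the
# package basis, individual columns are not.
truncated_power_natural_basis <- function(t, all_knots) {
  xi <- sort(all_knots)
  M <- length(xi)
  dk <- function(k) {
    (pmax(t - xi[k], 0)^3 - pmax(t - xi[M], 0)^3) / (xi[M] - xi[k])
  }
  dM1 <- dk(M - 1)
  cols <- cbind(1, t)
  for (k in seq_len(M - 2)) cols <- cbind(cols, dk(k) - dM1)
  cols
}

# residual of projecting each column of B onto the column space of A
max_projection_residual <- function(B, A) {
  fit <- A %*% qr.solve(qr(A), B)
  max(abs(B - fit))
}

# mean of N(mu, sd^2) truncated to (0, Inf)
tnorm_pos_mean <- function(mu, sd) {
  a <- -mu / sd
  mu + sd * exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

# analytic moments of the location-0 skew families
sn_mean <- function(delta) delta * sqrt(2 / pi)
sn_var <- function(sigma2, delta) sigma2 + delta^2 * (1 - 2 / pi)
st_mean <- function(delta, rho) {
  delta * sqrt(2 / pi) * sqrt(rho / 2) * exp(lgamma((rho - 1) / 2) - lgamma(rho / 2))
}

# hand-built design bundle (random intercept only unless R_cols given)
manual_bundle <- function(y, subject, Z, R_cols = NULL) {
  ord <- order(subject)
  y <- y[ord]; Z <- Z[ord, , drop = FALSE]
  subject <- subject[ord]
  R <- if (is.null(R_cols)) matrix(1, length(y), 1) else R_cols[ord, , drop = FALSE]
  len <- as.integer(table(factor(subject)))
  structure(list(
    y = y, Z = Z, R = R,
    start = c(0L, cumsum(len)[-length(len)]), len = len,
    m = length(len), n = length(y), p = ncol(Z), d = ncol(R),
    subjects = unique(as.character(subject)),
    z_names = colnames(Z) %||% paste0("z", seq_len(ncol(Z))),
    r_names = paste0("r", seq_len(ncol(R))),
    spline = NULL, linear_time = FALSE, covariates = character()
  ), class = "design_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bundle with m subjects and no observations (prior-only runs)
empty_bundle <- function(m, p = 1L, d = 1L) {
  structure(list(
    y = numeric(0), Z = matrix(0, 0, p), R = matrix(0, 0, d),
    start = seq_len(m) - 1L, len = rep(0L, m),
    m = as.integer(m), n = 0L, p = as.integer(p), d = as.integer(d),
    subjects = as.character(seq_len(m)),
    z_names = paste0("z", seq_len(p)), r_names = paste0("r", seq_len(d)),
    spline = NULL, linear_time = FALSE, covariates = character()
  ), class = "design_bundle")
}

# directly coded Gibbs sampler for the normal-normal random-intercept model
# y_ij = x_ij' beta + b_i + e_ij, b_i ~ N(0, tau2), e_ij ~ N(0, sigma2),
# priors beta ~ N(0, A0 I), sigma2 ~ IG(e1, e2), tau2 ~ IG(nu/2, D/2)
# (the 1-dimensional inverse-Wishart).  Independent of the package kernel.
direct_nn_gibbs <- function(y, X, subject, n_iter, burnin,
                            A0 = 100, e1 = 0.01, e2 = 0.01,
                            nu = 1, D = 0.01, seed = 1) {
  set.seed(seed)
  subject <- factor(subject)
  m <- nlevels(subject)
  idx <- split(seq_along(y), subject)
  p <- ncol(X)
  beta <- qr.solve(qr(X), y)
  b <- rep(0, m)
  sigma2 <- as.numeric(stats::var(y - X %*% beta))
  tau2 <- 1
  keep <- matrix(NA_real_, n_iter - burnin, p + 2)
  for (it in seq_len(n_iter)) {
    r <- y - b[as.integer(subject)]
    P <- crossprod(X) / sigma2 + diag(1 / A0, p)
    mu <- solve(P, crossprod(X, r) / sigma2)
    beta <- as.numeric(mu + backsolve(chol(P), rnorm(p)))
    e <- y - X %*% beta
    for (i in seq_len(m)) {
      ni <- length(idx[[i]])
      v <- 1 / (ni / sigma2 + 1 / tau2)
      b[i] <- rnorm(1, v * sum(e[idx[[i]]]) / sigma2, sqrt(v))
    }
    res <- as.numeric(e) - b[as.integer(subject)]
    sigma2 <- 1 / rgamma(1, e1 + length(y) / 2, rate = e2 + sum(res^2) / 2)
    tau2 <- 1 / rgamma(1, (nu + m) / 2, rate = (D + sum(b^2)) / 2)
    if (it > burnin) keep[it - burnin, ] <- c(beta, sigma2, tau2)
  }
  colnames(keep) <- c(paste0("beta", seq_len(p)), "sigma2", "tau2")
  keep
}

# sample skewness
sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
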