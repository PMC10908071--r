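#' Geweke convergence z-score
#'
#' Compares the mean of an early chain segment against a late segment,
#' standardized by spectral-density-at-zero variance estimates (Bartlett
#' lag-window estimator with window length 4% of the segment), so
#' autocorrelated draws are handled.  |z| above 1.96 flags a drifting chain.
#'
#' @param chain numeric vector of draws from one chain.
#' @param frac_first fraction of the chain forming the early window
#'   (default 0.1).
#' @param frac_last fraction forming the late window (default 0.5).
#' @return z statistic; a constant chain returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  n <- length(chain)
  if (n < 100) stop("geweke_z: chain must have at least 100 draws")
  if (frac_first + frac_last > 1) stop("geweke_z: window fractions overlap")
  if (stats::var(chain) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  a <- chain[seq_len(floor(frac_first * n))]
  b <- chain[seq.int(n - floor(frac_last * n) + 1L, n)]
  z <- (mean(a) - mean(b)) /
    sqrt(spectrum0(a) / length(a) + spectrum0(b) / length(b))
  structure(z, degenerate = FALSE)
}

# spectral density at frequency zero via a Bartlett lag window covering 4%
# of the segment length
spectrum0 <- function(x) {
  n <- length(x)
  L <- max(1L, floor(0.04 * n))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  g0 <- ac[1]
  if (L >= 1) {
    w <- 1 - seq_len(L) / (L + 1)
    g0 + 2 * sum(w * ac[-1])
  } else {
    g0
  }
}

#' Brooks-Gelman-Rubin potential scale reduction
#'
#' The scalar PSRF \eqn{\sqrt{((n-1)/n\,W + B/n)/W}} from between- and
#' within-chain variances.  Values near 1 indicate the chains have mixed
#' into a common distribution; the conventional threshold is 1.1.
#'
#' @param chains list of (or matrix with columns as) at least two
#'   equal-length numeric chains.
#' @return the PSRF statistic.
#' @export
bgr <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("bgr: at least two chains are required")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("bgr: chains must have equal lengths")
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Chain autocorrelation function
#'
#' Sample autocorrelations of a chain from lag 0 to `max_lag`.
#'
#' @param chain numeric vector of draws.
#' @param max_lag largest lag (must be below the chain length).
#' @return numeric vector of length `max_lag + 1`; element 1 is lag 0 (= 1).
#' @export
chain_acf <- function(chain, max_lag = 40L) {
  if (max_lag >= length(chain)) stop("chain_acf: max_lag must be below the chain length")
  as.numeric(stats::acf(chain, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf[, 1, 1])
}

#' Convergence diagnostics report
#'
#' Per-parameter convergence summary over the chains of a fit: Geweke
#' z-scores (worst chain), the Brooks-Gelman-Rubin statistic, lag-1 and
#' lag-10 autocorrelations, retained draw counts, and pass flags at
#' |z| < 1.96 and BGR < 1.1.  Parameters pinned by the model flavor (zero
#' variance) are flagged degenerate and pass trivially.
#'
#' @param chains an `splmm_chains` object (or list of draw matrices with
#'   common column names).
#' @param params optional subset of parameter names.
#' @param max_lag largest ACF lag retained.
#' @return a data.frame of class `"diagnostics_report"`, one row per
#'   parameter, with the full ACF in attribute `"acf"`.
#' @export
diagnostics_report <- function(chains, params = NULL, max_lag = 40L) {
  dl <- if (inherits(chains, "splmm_chains")) chains$draws else chains
  nm <- colnames(dl[[1]])
  params <- params %||% setdiff(nm, "deviance")
  acfs <- matrix(NA_real_, max_lag + 1L, length(params),
                 dimnames = list(NULL, params))
  out <- lapply(params, function(p) {
    cols <- lapply(dl, function(d) d[, p])
    degenerate <- all(vapply(cols, function(v) stats::var(v) == 0, TRUE))
    z <- if (degenerate) 0 else {
      zs <- vapply(cols, function(v) as.numeric(geweke_z(v)), 0)
      zs[which.max(abs(zs))]
    }
    r <- if (length(cols) >= 2) bgr(cols) else NA_real_
    a <- if (degenerate) c(1, rep(0, max_lag)) else chain_acf(cols[[1]], max_lag)
    acfs[, p] <<- a
    data.frame(parameter = p, geweke_z = z,
               bgr = r, acf1 = a[2], acf10 = if (max_lag >= 10) a[11] else NA,
               n_retained = sum(lengths(cols)),
               degenerate = degenerate,
               pass_geweke = abs(z) < 1.96,
               pass_bgr = is.na(r) | r < 1.1)
  })
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  attr(rep, "acf") <- acfs
  class(rep) <- c("diagnostics_report", "data.frame")
  rep
}

#' Write a diagnostics report as a delimited table
#'
#' @param report a [diagnostics_report()].
#' @param path output CSV path.
#' @export
write_diagnostics <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
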