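#' Posterior summary table
#'
#' Per-parameter posterior mean, standard deviation and 95% credible
#' interval from the pooled post-burn-in draws.  Equal-tailed (2.5%, 97.5%)
#' intervals by default; `hpd = TRUE` gives highest-posterior-density
#' intervals instead.
#'
#' @param chains an `splmm_chains` fit, a draw matrix, or a list of draw
#'   matrices.
#' @param prob interval probability (default 0.95).
#' @param hpd use HPD intervals.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(chains, prob = 0.95, hpd = FALSE) {
  pool <- if (inherits(chains, "splmm_chains")) {
    as.matrix(chains)
  } else if (is.list(chains) && !is.data.frame(chains)) {
    do.call(rbind, chains)
  } else {
    as.matrix(chains)
  }
  if (nrow(pool) == 0L) stop("posterior_summary: empty chain")
  a <- (1 - prob) / 2
  out <- lapply(colnames(pool), function(p) {
    x <- pool[, p]
    ci <- if (hpd) hpd_interval(x, prob) else {
      unname(stats::quantile(x, c(a, 1 - a), names = FALSE))
    }
    data.frame(parameter = p, mean = mean(x),
               sd = stats::sd(x), lower = ci[1], upper = ci[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# shortest interval containing prob of the sorted draws
hpd_interval <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(range(x))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Write a posterior summary table
#'
#' @param chains an `splmm_chains` fit.
#' @param path output CSV path.
#' @param ... passed to [posterior_summary()].
#' @return the summary data.frame, invisibly.
#' @export
write_posterior_summary <- function(chains, path, ...) {
  s <- posterior_summary(chains, ...)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(s)
}

#' Write chains as a columnar text archive
#'
#' One row per retained draw with a chain identifier and iteration index,
#' one column per named parameter; a companion `<path>.meta.json`-style file
#' is not used -- metadata needed to re-read the archive travels in the
#' header row alone, keeping the format plain CSV.
#'
#' @param chains an `splmm_chains` fit.
#' @param path output CSV path.
#' @export
write_chains <- function(chains, path) {
  stopifnot(inherits(chains, "splmm_chains"))
  tabs <- lapply(seq_along(chains$draws), function(ch) {
    d <- chains$draws[[ch]]
    cbind(data.frame(chain = ch, iteration = seq_len(nrow(d))),
          as.data.frame(d, check.names = FALSE))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read a chain archive
#'
#' Rebuilds the per-chain draw matrices from a [write_chains()] archive.
#' Only draws travel through the archive (no design or latent means), so the
#' result supports summaries and convergence diagnostics but not latent-
#' dependent quantities.
#'
#' @param path CSV path.
#' @return list of draw matrices, one per chain, of class
#'   `"splmm_chain_archive"`.
#' @export
read_chains <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("chain", "iteration") %in% names(df)))
  pars <- setdiff(names(df), c("chain", "iteration"))
  out <- lapply(split(df, df$chain), function(s) {
    as.matrix(s[order(s$iteration), pars, drop = FALSE])
  })
  names(out) <- NULL
  structure(out, class = "splmm_chain_archive")
}
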