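#' Simulation design for skewed longitudinal trajectories
#'
#' The study conditions of the package's evaluation harness: `m` subjects
#' observed on a common equally spaced time grid; response built from an
#' intercept, two subject-level Bernoulli covariates, three natural cubic
#' spline bases of time with subject-specific coefficient deviations, a
#' random intercept, and i.i.d. errors; every random effect component and
#' error drawn from a shifted gamma law, Gamma(shape 2, scale 1) minus 2,
#' which is mean zero with variance 2 and skewness sqrt(2).
#'
#' @param m number of subjects (default 400).
#' @param times common measurement grid (default 0, 1, ..., 10).
#' @param alpha_true intercept and the two covariate effects.
#' @param lambda_true the three population spline coefficients.
#' @param covariate_probs Bernoulli probabilities of the two subject-level
#'   binary covariates.
#' @param gamma_shape,gamma_scale,gamma_shift parameters of the shifted gamma
#'   law used for random effects and errors.
#' @param spline spline specification (default 2 interior percentile knots,
#'   giving 3 basis columns).
#' @return a list of class `"sim_design"`.
#' @export
sim_design <- function(m = 400L, times = 0:10,
                       alpha_true = c(27.5, -5, -4),
                       lambda_true = c(-9, -25, -5),
                       covariate_probs = c(0.24, 0.44),
                       gamma_shape = 2, gamma_scale = 1, gamma_shift = -2,
                       spline = spline_spec(n_interior = 2L)) {
  stopifnot(m >= 1L, length(times) >= 2L, !is.unsorted(times, strictly = TRUE),
            all(covariate_probs > 0 & covariate_probs < 1),
            length(alpha_true) == 1L + length(covariate_probs))
  if (abs(gamma_shape * gamma_scale + gamma_shift) > 1e-12) {
    warning("sim_design: shifted gamma law is not mean zero")
  }
  structure(list(m = as.integer(m), times = as.numeric(times),
                 alpha_true = alpha_true, lambda_true = lambda_true,
                 covariate_probs = covariate_probs,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 gamma_shift = gamma_shift, spline = spline),
            class = "sim_design")
}

# one draw of the shifted gamma law
rshifted_gamma <- function(n, design) {
  stats::rgamma(n, shape = design$gamma_shape, scale = design$gamma_scale) +
    design$gamma_shift
}

#' Simulate one skewed longitudinal dataset
#'
#' Generates responses as
#' \deqn{y_{ij} = \alpha_1 + \alpha_2 Z_{1i} + \alpha_3 Z_{2i} + \varphi_{i1}
#'   + \sum_{k=1}^{3} (\lambda_k + \varphi_{i,k+1}) \phi_k(t_{ij})
#'   + \varepsilon_{ij},}
#' with the spline bases \eqn{\phi_k} built from percentile knots of the time
#' grid, subject-constant Bernoulli covariates, and all four random-effect
#' components and errors i.i.d. shifted gamma.
#'
#' @param design a [sim_design()].
#' @param seed integer seed.
#' @return list with `data` (a [longitudinal_data()]), `truth` (every
#'   generating value: coefficients, per-subject random effects, knots,
#'   covariate draws, and the generating-law summary), and `basis` (the
#'   spline basis on the grid).
#' @export
simulate_dataset <- function(design = sim_design(), seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  m <- design$m
  tt <- design$times
  nt <- length(tt)
  B <- natural_cubic_basis(rep(tt, m), design$spline)
  l <- ncol(B)
  stopifnot(length(design$lambda_true) == l)
  Zb <- vapply(design$covariate_probs,
               function(p) stats::rbinom(m, 1, p), integer(m))
  phi <- matrix(rshifted_gamma(m * (l + 1L), design), m, l + 1L)
  eps <- rshifted_gamma(m * nt, design)
  subj <- rep(seq_len(m), each = nt)
  fixed <- design$alpha_true[1] +
    as.numeric(Zb %*% design$alpha_true[-1])[subj]
  spl <- rowSums(B * (matrix(design$lambda_true, m * nt, l, byrow = TRUE) +
                        phi[subj, -1, drop = FALSE]))
  y <- fixed + phi[subj, 1] + spl + eps
  df <- data.frame(subject = subj, time = rep(tt, m), response = y,
                   Z1 = Zb[subj, 1], Z2 = Zb[subj, 2])
  data <- longitudinal_data(df, covariates = c("Z1", "Z2"),
                            min_visits = min(3L, nt))
  truth <- list(alpha = design$alpha_true, lambda = design$lambda_true,
                phi = phi, covariates = Zb, eps = eps,
                interior_knots = attr(B, "interior_knots"),
                boundary_knots = attr(B, "boundary_knots"),
                law = sprintf("Gamma(shape %g, scale %g) %+g",
                              design$gamma_shape, design$gamma_scale,
                              design$gamma_shift),
                seed = seed)
  list(data = data, truth = truth,
       basis = B[seq_len(nt), , drop = FALSE])
}

#' Replication metrics: Est, RB, RMSE, CP
#'
#' Aggregates per-replication posterior means and 95% credible intervals
#' against the generating values: `Est` is the mean posterior mean, relative
#' bias `RB = (Est - TV)/TV`, `RMSE` the root mean squared error of the
#' per-replication estimates, and `CP` the percentage of replications whose
#' interval covers the truth.  A zero true value makes RB undefined; the
#' absolute bias is reported instead with `rb_is_absolute` flagged.
#'
#' @param estimates replications-by-parameters matrix of posterior means
#'   (column names identify parameters).
#' @param lower,upper matching matrices of 95% interval endpoints, or `NULL`
#'   to skip CP.
#' @param truths named vector of generating values.
#' @return data.frame with one row per parameter.
#' @export
evaluate_metrics <- function(estimates, lower = NULL, upper = NULL, truths) {
  estimates <- as.matrix(estimates)
  nm <- colnames(estimates)
  stopifnot(!is.null(nm), all(nm %in% names(truths)))
  out <- lapply(nm, function(p) {
    tv <- truths[[p]]
    est <- mean(estimates[, p])
    rb_abs <- tv == 0
    rb <- if (rb_abs) est - tv else (est - tv) / tv
    rmse <- sqrt(mean((estimates[, p] - tv)^2))
    cp <- if (is.null(lower)) NA_real_ else {
      100 * mean(lower[, p] <= tv & tv <= upper[, p])
    }
    data.frame(parameter = p, TV = tv, Est = est, RB = rb, RMSE = rmse,
               CP = cp, rb_is_absolute = rb_abs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# posterior means and equal-tailed 95% intervals for selected parameters
fit_estimates <- function(fit, params) {
  pool <- as.matrix(fit)
  est <- colMeans(pool[, params, drop = FALSE])
  qs <- apply(pool[, params, drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  list(est = est, lower = qs[1, ], upper = qs[2, ])
}

#' Replication study over model flavors
#'
#' The package's evaluation engine: repeatedly simulate from the design, fit
#' every requested model flavor with independently seeded chains, and
#' aggregate fixed-effect recovery metrics and DIC per flavor.  Fully
#' deterministic given the master seed; optional per-replication text
#' checkpoints make long runs resumable.
#'
#' @param design a [sim_design()].
#' @param configs named list of [model_config()]s (names default to
#'   [model_label()]).
#' @param R number of replications.
#' @param mcmc an [mcmc_control()] applied to every fit (its seed is
#'   re-derived per replication and flavor).
#' @param seed master seed.
#' @param checkpoint_dir optional directory for per-replication CSV
#'   checkpoints; existing checkpoints are reused.
#' @param verbose print one line per replication.
#' @return list of class `"simulation_result"`: `metrics` (per-flavor
#'   data.frame from [evaluate_metrics()]), `dic` (replications-by-flavors
#'   matrix), `estimates` (per-flavor matrices), `failures`, `meta`.
#' @export
run_replications <- function(design = sim_design(), configs,
                             R = 100L, mcmc = mcmc_control(chains = 2L),
                             seed = 1L, checkpoint_dir = NULL,
                             verbose = FALSE) {
  stopifnot(R >= 1L, length(configs) >= 1L)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, model_label, "")
  }
  flavors <- names(configs)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 R * (length(flavors) + 1L)),
                      R, length(flavors) + 1L)
  est <- low <- upp <- list()
  dic_mat <- matrix(NA_real_, R, length(flavors),
                    dimnames = list(NULL, flavors))
  failures <- data.frame(replication = integer(), flavor = character(),
                         message = character())
  truths <- NULL

  for (r in seq_len(R)) {
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("replication_%04d.csv", r))
    } else NULL
    if (!is.null(ck) && file.exists(ck)) {
      rows <- utils::read.csv(ck, stringsAsFactors = FALSE)
    } else {
      sim <- simulate_dataset(design, seed = rep_seeds[r, 1])
      rows <- NULL
      for (fi in seq_along(flavors)) {
        fl <- flavors[fi]
        cfg <- configs[[fl]]
        mc <- mcmc
        mc$seed <- rep_seeds[r, fi + 1L]
        fit <- tryCatch(run_mcmc(sim$data, cfg, mcmc = mc), error = identity)
        if (inherits(fit, "error")) {
          failures <- rbind(failures, data.frame(
            replication = r, flavor = fl, message = conditionMessage(fit)))
          next
        }
        pars <- grep("^alpha\\[", fit$params, value = TRUE)
        es <- fit_estimates(fit, pars)
        rows <- rbind(rows, data.frame(
          replication = r, flavor = fl, parameter = pars,
          est = unname(es$est), lower = unname(es$lower),
          upper = unname(es$upper), dic = dic(fit)$dic))
      }
      if (!is.null(ck) && !is.null(rows)) {
        utils::write.csv(rows, ck, row.names = FALSE)
      }
    }
    if (is.null(rows)) next
    for (fl in unique(rows$flavor)) {
      sub <- rows[rows$flavor == fl, ]
      if (is.null(est[[fl]])) {
        est[[fl]] <- low[[fl]] <- upp[[fl]] <-
          matrix(NA_real_, R, length(sub$parameter),
                 dimnames = list(NULL, sub$parameter))
      }
      est[[fl]][r, sub$parameter] <- sub$est
      low[[fl]][r, sub$parameter] <- sub$lower
      upp[[fl]][r, sub$parameter] <- sub$upper
      dic_mat[r, fl] <- sub$dic[1]
    }
    if (verbose) message(sprintf("replication %d/%d done", r, R))
  }

  if (nrow(failures) > 0.1 * R * length(flavors)) {
    stop("run_replications: more than 10% of fits failed")
  }
  # generating values in sampler parameter naming: intercept, covariates,
  # then the spline block
  d0 <- design
  nz <- length(d0$covariate_probs)
  truths <- c(d0$alpha_true, d0$lambda_true)
  names(truths) <- c("alpha[(Intercept)]",
                     paste0("alpha[Z", seq_len(nz), "]"),
                     paste0("alpha[ns", seq_along(d0$lambda_true), "]"))
  metrics <- lapply(flavors, function(fl) {
    ok <- stats::complete.cases(est[[fl]])
    keep <- intersect(colnames(est[[fl]]), names(truths))
    evaluate_metrics(est[[fl]][ok, keep, drop = FALSE],
                     low[[fl]][ok, keep, drop = FALSE],
                     upp[[fl]][ok, keep, drop = FALSE], truths)
  })
  names(metrics) <- flavors
  structure(list(metrics = metrics, dic = dic_mat,
                 estimates = est, lower = low, upper = upp,
                 failures = failures,
                 meta = list(R = R, seed = seed, mcmc = mcmc,
                             design = design)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Replication study: R = %d, flavors: %s\n",
              x$meta$R, paste(names(x$metrics), collapse = ", ")))
  ok <- stats::complete.cases(x$dic)
  if (any(ok)) {
    cat("mean DIC:\n")
    print(round(colMeans(x$dic[ok, , drop = FALSE]), 2))
  }
  for (fl in names(x$metrics)) {
    cat("\n--", fl, "--\n")
    print(x$metrics[[fl]], digits = 4)
  }
  invisible(x)
}

#' Write replication metrics as delimited tables
#'
#' One CSV per flavor plus a DIC table, mirroring the usual
#' Est/RB/RMSE/CP-by-model simulation layout.
#'
#' @param result a [run_replications()] result.
#' @param dir output directory (created if absent).
#' @export
write_simulation_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fl in names(result$metrics)) {
    utils::write.csv(result$metrics[[fl]],
                     file.path(dir, paste0("metrics_", fl, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(result$dic), file.path(dir, "dic.csv"),
                   row.names = FALSE)
  invisible(dir)
}
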