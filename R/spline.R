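#' Interior knots at equally spaced percentiles
#'
#' Places `n_interior` knots at the 100*k/(n_interior+1) percentiles
#' (k = 1, ..., n_interior) of the observed measurement times, the usual
#' automatic knot rule for regression splines on irregular follow-up grids.
#' Percentiles use linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7).
#'
#' @param times numeric vector of observed measurement times.
#' @param n_interior non-negative integer number of interior knots.
#' @return numeric vector of interior knots, with the boundary knots
#'   (min/max of `times`) attached as attribute `"boundary"`.
#' @examples
#' percentile_knots(0:10, 2)
#' @export
percentile_knots <- function(times, n_interior) {
  if (length(times) == 0L || !is.numeric(times)) {
    stop("percentile_knots: 'times' must be a non-empty numeric vector")
  }
  if (any(!is.finite(times))) stop("percentile_knots: non-finite times")
  n_interior <- as.integer(n_interior)
  if (is.na(n_interior) || n_interior < 0L) {
    stop("percentile_knots: 'n_interior' must be a non-negative integer")
  }
  n_distinct <- length(unique(times))
  if (n_interior > n_distinct) {
    stop(sprintf(
      "percentile_knots: %d interior knots requested but only %d distinct times available",
      n_interior, n_distinct
    ))
  }
  bnd <- range(times)
  if (n_interior == 0L) {
    knots <- numeric(0)
  } else {
    probs <- seq_len(n_interior) / (n_interior + 1)
    knots <- unname(stats::quantile(times, probs = probs, type = 7))
    if (any(diff(c(bnd[1], knots, bnd[2])) <= 0)) {
      stop("percentile_knots: percentile knots are not strictly increasing between the boundaries; reduce 'n_interior'")
    }
  }
  structure(knots, boundary = bnd)
}

#' Natural cubic spline specification
#'
#' Describes the spline block shared by the population-level time effect and
#' the subject-specific time deviations: a natural cubic spline (piecewise
#' cubic, twice continuously differentiable, linear beyond the boundary
#' knots).  The basis has `n_interior + 1` columns when the intercept is
#' excluded; the model intercept lives in the parametric fixed-effect block.
#'
#' @param n_interior number of interior knots, ignored when `interior_knots`
#'   is given.
#' @param interior_knots optional ordered interior knot locations.
#' @param boundary_knots optional length-2 vector (lo < hi).  When omitted the
#'   knots are resolved from the data at design-build time via
#'   [percentile_knots()].
#' @param include_intercept include a constant column (default `FALSE`).
#' @return an object of class `"spline_spec"`.
#' @export
spline_spec <- function(n_interior = 2L, interior_knots = NULL,
                        boundary_knots = NULL, include_intercept = FALSE) {
  if (!is.null(interior_knots)) {
    interior_knots <- as.numeric(interior_knots)
    if (anyDuplicated(interior_knots) || is.unsorted(interior_knots, strictly = TRUE)) {
      stop("spline_spec: interior knots must be strictly increasing and distinct")
    }
    n_interior <- length(interior_knots)
  }
  if (!is.null(boundary_knots)) {
    boundary_knots <- as.numeric(boundary_knots)
    if (length(boundary_knots) != 2L || boundary_knots[1] >= boundary_knots[2]) {
      stop("spline_spec: boundary_knots must be c(lo, hi) with lo < hi")
    }
    if (!is.null(interior_knots) &&
        (any(interior_knots <= boundary_knots[1]) ||
         any(interior_knots >= boundary_knots[2]))) {
      stop("spline_spec: interior knots must lie strictly between the boundary knots")
    }
  }
  structure(
    list(
      n_interior = as.integer(n_interior),
      interior_knots = interior_knots,
      boundary_knots = boundary_knots,
      include_intercept = isTRUE(include_intercept)
    ),
    class = "spline_spec"
  )
}

# resolve data-dependent knots once, returning a fully specified spec
resolve_spline_spec <- function(spec, times) {
  stopifnot(inherits(spec, "spline_spec"))
  if (is.null(spec$interior_knots)) {
    k <- percentile_knots(times, spec$n_interior)
    spec$interior_knots <- as.numeric(k)
    if (is.null(spec$boundary_knots)) {
      spec$boundary_knots <- attr(k, "boundary")
    }
  } else if (is.null(spec$boundary_knots)) {
    spec$boundary_knots <- range(times)
  }
  if (length(spec$interior_knots) &&
      (any(spec$interior_knots <= spec$boundary_knots[1]) ||
       any(spec$interior_knots >= spec$boundary_knots[2]))) {
    stop("spline knots must lie strictly between the boundary knots")
  }
  spec
}

#' Evaluate the natural cubic spline basis
#'
#' Returns the basis matrix for the time effect.  Evaluation outside the
#' boundary knots extrapolates linearly, as natural splines do, so follow-up
#' times in new data may exceed the fitting range.
#'
#' @param times numeric vector of evaluation times.
#' @param spec a [spline_spec()]; data-dependent knots are resolved from
#'   `times` if not fixed in the spec.
#' @return numeric matrix, `length(times)` rows and `n_interior + 1` columns
#'   (one more with the intercept); resolved knots attached as attributes
#'   `"interior_knots"` and `"boundary_knots"`.
#' @export
natural_cubic_basis <- function(times, spec = spline_spec()) {
  spec <- resolve_spline_spec(spec, times)
  allk <- c(spec$boundary_knots[1], spec$interior_knots, spec$boundary_knots[2])
  if (anyDuplicated(allk)) stop("natural_cubic_basis: degenerate (duplicated) knots")
  B <- splines::ns(
    times,
    knots = if (length(spec$interior_knots)) spec$interior_knots else NULL,
    Boundary.knots = spec$boundary_knots,
    intercept = spec$include_intercept
  )
  B <- unclass(B)[, , drop = FALSE]
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  attr(B, "interior_knots") <- spec$interior_knots
  attr(B, "boundary_knots") <- spec$boundary_knots
  B
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Natural cubic spline spec\n")
  if (is.null(x$interior_knots)) {
    cat("  interior knots:", x$n_interior, "(percentile-based, resolved from data)\n")
  } else {
    cat("  interior knots:", paste(signif(x$interior_knots, 4), collapse = ", "), "\n")
  }
  if (!is.null(x$boundary_knots)) {
    cat("  boundary knots:", paste(signif(x$boundary_knots, 4), collapse = ", "), "\n")
  }
  cat("  intercept:", x$include_intercept, "\n")
  invisible(x)
}
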