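#' Long-format longitudinal dataset
#'
#' Validates and types a long-format table (one row per subject-visit) for
#' model fitting.  Subjects with fewer than `min_visits` visits and rows with
#' missing responses are dropped, with counts reported via `message()` so the
#' effective sample size is always reproducible from the log.
#'
#' @param data a data.frame.
#' @param subject,time,response column names for the subject identifier,
#'   measurement time and continuous response.
#' @param covariates character vector of covariate column names (binary or
#'   continuous), possibly empty.
#' @param min_visits minimum visits a subject must have to be retained
#'   (default 3, the usual inclusion rule for follow-up studies).
#' @return an object of class `"longitudinal_data"`: the filtered data.frame
#'   ordered by subject and time, with the column mapping in attributes.
#' @export
longitudinal_data <- function(data, subject = "subject", time = "time",
                              response = "response", covariates = character(),
                              min_visits = 3L) {
  stopifnot(is.data.frame(data))
  needed <- c(subject, time, response, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("longitudinal_data: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(data)[, needed, drop = FALSE]
  names(df) <- c("subject", "time", "response", covariates)
  if (!is.numeric(df$time)) stop("longitudinal_data: 'time' must be numeric")
  if (!is.numeric(df$response)) stop("longitudinal_data: 'response' must be numeric")
  if (any(!is.finite(df$time))) stop("longitudinal_data: non-finite times")
  for (cv in covariates) {
    if (!is.numeric(df[[cv]])) stop("longitudinal_data: covariate '", cv, "' must be numeric")
  }

  n_miss <- sum(is.na(df$response))
  if (n_miss > 0) {
    message(sprintf("longitudinal_data: dropped %d row(s) with missing response", n_miss))
    df <- df[!is.na(df$response), , drop = FALSE]
  }
  df$subject <- factor(df$subject)
  visits <- table(df$subject)
  too_few <- names(visits)[visits < min_visits]
  if (length(too_few)) {
    message(sprintf(
      "longitudinal_data: dropped %d subject(s) with fewer than %d visits",
      length(too_few), min_visits
    ))
    df <- df[!(df$subject %in% too_few), , drop = FALSE]
    df$subject <- droplevels(df$subject)
  }
  if (nrow(df) == 0L || nlevels(df$subject) == 0L) {
    stop("longitudinal_data: no subjects remain after filtering")
  }
  df <- df[order(df$subject, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            covariates = covariates,
            min_visits = as.integer(min_visits),
            n_dropped_subjects = length(too_few),
            n_dropped_rows = n_miss,
            class = c("longitudinal_data", "data.frame"))
}

#' Read a long-format CSV into a longitudinal dataset
#'
#' @param path path to a delimited text file with a header.
#' @param mapping named list with entries `subject`, `time`, `response` and
#'   optionally `covariates` giving the column names in the file.
#' @param min_visits minimum visits per subject (default 3).
#' @param sep field separator (default `","`).
#' @return a [longitudinal_data()] object.
#' @export
read_long_csv <- function(path, mapping = list(subject = "subject",
                                               time = "time",
                                               response = "response",
                                               covariates = character()),
                          min_visits = 3L, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  covs <- mapping$covariates %||% character()
  longitudinal_data(df,
                    subject = mapping$subject, time = mapping$time,
                    response = mapping$response, covariates = covs,
                    min_visits = min_visits)
}

#' Write a longitudinal dataset as CSV
#'
#' @param data a [longitudinal_data()] object (or plain data.frame).
#' @param path output file path.
#' @export
write_long_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.longitudinal_data <- function(x, ...) {
  cat(sprintf("Longitudinal dataset: %d rows, %d subjects, %d covariate(s)\n",
              nrow(x), nlevels(x$subject), length(attr(x, "covariates"))))
  NextMethod()
}
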