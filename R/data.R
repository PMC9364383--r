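#' Construct a validated right-censored survival dataset
#'
#' Bundles observed times, event indicators and a covariate matrix into the
#' container used by every fitting and simulation function in the package.
#'
#' @param time numeric vector of strictly positive observed times.
#' @param status integer/numeric vector of event indicators; 1 = event
#'   observed, 0 = right-censored.
#' @param X numeric matrix of covariates, one row per subject.
#' @param feature_names optional character vector of column identifiers;
#'   defaults to existing column names or `V1..Vp`.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `time`, `status` and `X` (with column names set).
#' @export
survival_dataset <- function(time, status, X, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  time <- as.numeric(time)
  status <- as.integer(status)
  n <- length(time)
  if (length(status) != n || nrow(X) != n)
    stop("time, status and rows of X must have equal length")
  if (anyNA(time) || anyNA(status) || anyNA(X)) {
    bad <- which(rowSums(is.na(cbind(time, status, X))) > 0)[1L]
    stop(sprintf("missing values are not allowed (first offending row: %d)", bad))
  }
  if (any(time <= 0))
    stop(sprintf("all times must be strictly positive (row %d violates this)",
                 which(time <= 0)[1L]))
  if (!all(status %in% c(0L, 1L)))
    stop(sprintf("status must be 0 or 1 (row %d violates this)",
                 which(!(status %in% c(0L, 1L)))[1L]))
  if (is.null(feature_names)) {
    feature_names <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  }
  if (length(feature_names) != ncol(X))
    stop("feature_names must match the number of covariate columns")
  colnames(X) <- feature_names
  structure(list(time = time, status = status, X = X),
            class = "survival_dataset")
}

#' @exportS3Method base::print
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> n = %d, p = %d, events = %d (%.1f%% censored)\n",
              length(x$time), ncol(x$X), sum(x$status),
              100 * mean(x$status == 0)))
  invisible(x)
}

#' @export
dim.survival_dataset <- function(x) c(length(x$time), ncol(x$X))

#' Read a survival dataset from a delimited text file
#'
#' Expects a header row with a time column, a 0/1 status column, and at
#' least one covariate column; all remaining columns are taken as covariates.
#'
#' @param path file path.
#' @param time_col,status_col column names holding the observed time and the
#'   event indicator.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return A [survival_dataset()].
#' @export
read_survival_dataset <- function(path, time_col = "time",
                                  status_col = "status",
                                  format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  df <- if (format == "tsv") read.delim(path, check.names = FALSE)
        else read.csv(path, check.names = FALSE)
  for (col in c(time_col, status_col)) {
    if (!col %in% names(df))
      stop(sprintf("schema error: required column '%s' not found", col))
  }
  covars <- setdiff(names(df), c(time_col, status_col))
  if (length(covars) == 0) stop("schema error: no covariate columns found")
  survival_dataset(df[[time_col]], df[[status_col]],
                   as.matrix(df[covars]), feature_names = covars)
}

#' Write a survival dataset as a delimited text file
#'
#' @param data a [survival_dataset()].
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @param sidecar optional path for a JSON sidecar recording centering means
#'   and retained features when the data carry them (see
#'   [center_covariates()], [cv_filter()]).
#' @return `path`, invisibly.
#' @export
write_survival_dataset <- function(data, path, sidecar = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  df <- data.frame(time = data$time, status = data$status, data$X,
                   check.names = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    meta <- list(centers = attr(data, "centers"),
                 retained = attr(data, "retained"))
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Risk sets for the Cox partial likelihood
#'
#' For every subject with an observed event, the risk set is the index set
#' of subjects whose observed time is at least the event time
#' (ties included, so tied event times share identical risk sets).
#'
#' @param data a [survival_dataset()].
#' @return A list of class `risk_set_index` with `event_order` (row indices
#'   of uncensored subjects, ordered by time then row index) and
#'   `risk_members` (for each such subject, the sorted indices of its risk
#'   set).
#' @export
build_risk_sets <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  ev <- which(data$status == 1L)
  if (length(ev) == 0)
    stop("no events: the partial likelihood is undefined without at least one uncensored subject")
  ev <- ev[order(data$time[ev], ev)]
  members <- lapply(ev, function(i) which(data$time >= data$time[i]))
  structure(list(event_order = ev, risk_members = members),
            class = "risk_set_index")
}

#' Center the covariate columns at zero
#'
#' The column means are retained (attribute `"centers"`) so the identical
#' shift can be applied to held-out data with [apply_centering()].
#'
#' @param data a [survival_dataset()].
#' @return The dataset with centered covariates.
#' @export
center_covariates <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  centers <- colMeans(data$X)
  out <- data
  out$X <- sweep(data$X, 2, centers)
  attr(out, "centers") <- centers
  attr(out, "retained") <- attr(data, "retained")
  out
}

#' Apply a previously computed centering to new data
#'
#' @param data a [survival_dataset()] whose columns match `centers`.
#' @param centers named numeric vector of column means from
#'   [center_covariates()].
#' @return The shifted dataset.
#' @export
apply_centering <- function(data, centers) {
  stopifnot(inherits(data, "survival_dataset"),
            length(centers) == ncol(data$X))
  out <- data
  out$X <- sweep(data$X, 2, centers)
  attr(out, "centers") <- centers
  out
}

#' Filter features by coefficient of variation
#'
#' Retains the covariate columns whose coefficient of variation (sd/mean)
#' is at least the median coefficient of variation across columns. Intended
#' for nonnegative expression-scale matrices before centering; columns with
#' zero mean are assigned an infinite coefficient of variation (always
#' retained) with a warning.
#'
#' @param data a [survival_dataset()] with uncentered covariates.
#' @return The filtered dataset; retained feature names are recorded in the
#'   `"retained"` attribute.
#' @export
cv_filter <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  mu <- colMeans(data$X)
  s <- apply(data$X, 2, sd)
  cv <- s / mu
  if (any(mu == 0)) {
    warning(sprintf("%d zero-mean column(s) assigned infinite coefficient of variation",
                    sum(mu == 0)))
    cv[mu == 0] <- Inf
  }
  keep <- cv >= median(cv)
  out <- data
  out$X <- data$X[, keep, drop = FALSE]
  attr(out, "retained") <- colnames(data$X)[keep]
  out
}

# internal: sort subjects by time and precompute the quantities the C++
# routines need (0-based event positions and per-event risk-set start)
svb_prepare <- function(data) {
  ord <- order(data$time, seq_along(data$time))
  t_s <- data$time[ord]
  ev_pos <- which(data$status[ord] == 1L)
  if (length(ev_pos) == 0)
    stop("no events: the partial likelihood is undefined without at least one uncensored subject")
  rs <- match(t_s[ev_pos], t_s)
  list(order = ord, X = data$X[ord, , drop = FALSE], time = t_s,
       ev = as.integer(ev_pos - 1L), rs = as.integer(rs - 1L),
       n = length(t_s), p = ncol(data$X))
}
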