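#' Construct a right-censored survival sample
#'
#' Bundles follow-up times, event indicators and the two covariate blocks
#' used by cure models: `X` enters the incidence (or long-term) component,
#' `Z` the latency (or short-term) component.  The blocks may share columns,
#' overlap, or be completely distinct.
#'
#' @param time Numeric vector of nonnegative follow-up times.
#' @param status Integer/numeric vector of event indicators, 1 = event,
#'   0 = right-censored.
#' @param X Optional numeric matrix (or vector) of incidence covariates,
#'   one row per subject.
#' @param Z Optional numeric matrix (or vector) of latency covariates.
#'
#' @return An object of class `"survival_sample"`: a list with elements
#'   `time`, `status`, `X`, `Z` and `n`.  `X` and `Z` are always matrices
#'   (possibly with zero columns).
#' @examples
#' s <- survival_sample(c(1, 2, 3, 4), c(1, 0, 1, 0))
#' s$n
#' @export
survival_sample <- function(time, status, X = NULL, Z = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  n <- length(time)
  if (n < 1L) stop("empty sample")
  if (length(status) != n) stop("'time' and 'status' lengths differ")
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and nonnegative")
  if (!all(status %in% c(0, 1)))
    stop("'status' must contain only 0 (censored) and 1 (event)")
  as_block <- function(M, nm) {
    if (is.null(M)) return(matrix(numeric(0), nrow = n, ncol = 0))
    M <- as.matrix(M)
    if (nrow(M) != n) stop(sprintf("'%s' must have one row per subject", nm))
    storage.mode(M) <- "double"
    if (anyNA(M) || any(!is.finite(M))) stop(sprintf("'%s' has missing values", nm))
    if (ncol(M) > 0 && is.null(colnames(M)))
      colnames(M) <- paste0(nm, seq_len(ncol(M)))
    M
  }
  structure(list(time = time, status = status,
                 X = as_block(X, "X"), Z = as_block(Z, "Z"), n = n),
            class = "survival_sample")
}

#' @export
print.survival_sample <- function(x, ...) {
  cat(sprintf("survival_sample: n = %d, events = %d (%.1f%% censored)\n",
              x$n, sum(x$status), 100 * mean(x$status == 0)))
  cat(sprintf("  incidence covariates: %d, latency covariates: %d\n",
              ncol(x$X), ncol(x$Z)))
  invisible(x)
}

# Unvalidated row subset; used by the leave-one-out loops where the
# constructor's checks would dominate the run time.
sample_subset <- function(sample, keep) {
  structure(list(time = sample$time[keep], status = sample$status[keep],
                 X = sample$X[keep, , drop = FALSE],
                 Z = sample$Z[keep, , drop = FALSE],
                 n = length(sample$time[keep])),
            class = "survival_sample")
}

#' Read a survival sample from a delimited text file
#'
#' Reads a subject-level table (one row per subject) and validates it into
#' a [survival_sample()].  Character or factor covariates are one-hot
#' encoded deterministically: categories are sorted and the first level is
#' dropped.  Rows with missing values in any used column are removed with
#' a warning, mirroring the usual complete-case preprocessing of clinical
#' tables.
#'
#' @param path Path to a delimited text file with a header row.
#' @param time,status Column names of the follow-up time and the 0/1 event
#'   indicator.
#' @param incidence,latency Character vectors naming the covariate columns
#'   for each component (either may be `NULL`).
#' @param sep Field separator, default comma.
#' @return A [survival_sample()].
#' @export
read_survival_csv <- function(path, time = "time", status = "status",
                              incidence = NULL, latency = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  used <- unique(c(time, status, incidence, latency))
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, used, drop = FALSE]
  cc <- stats::complete.cases(df)
  if (!all(cc)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!cc)))
    df <- df[cc, , drop = FALSE]
  }
  if (!all(df[[status]] %in% c(0, 1)))
    stop(sprintf("column '%s' is not a 0/1 event indicator", status))
  encode <- function(cols) {
    if (is.null(cols)) return(NULL)
    blocks <- lapply(cols, function(cl) {
      v <- df[[cl]]
      if (is.numeric(v)) {
        m <- matrix(v, ncol = 1, dimnames = list(NULL, cl))
      } else {
        lev <- sort(unique(as.character(v)))
        if (length(lev) < 2)
          stop(sprintf("covariate '%s' is constant", cl))
        m <- sapply(lev[-1], function(l) as.numeric(v == l))
        colnames(m) <- paste0(cl, lev[-1])
      }
      m
    })
    do.call(cbind, blocks)
  }
  survival_sample(df[[time]], df[[status]],
                  X = encode(incidence), Z = encode(latency))
}

#' Write a survival sample to CSV
#'
#' Inverse of [read_survival_csv()] for numeric covariates: columns
#' `time`, `status`, then the incidence and latency blocks.
#'
#' @param sample A [survival_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(sample, path) {
  df <- data.frame(time = sample$time, status = sample$status)
  if (ncol(sample$X)) df <- cbind(df, as.data.frame(sample$X))
  if (ncol(sample$Z)) {
    zdf <- as.data.frame(sample$Z)
    zdf <- zdf[, setdiff(names(zdf), names(df)), drop = FALSE]
    df <- cbind(df, zdf)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
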