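# A "series" is a numeric vector (univariate) or a numeric matrix with
# features in rows and time in columns (multivariate). Feature IDs are the
# matrix rownames. All engine code funnels through these helpers so that the
# two representations behave identically.

series_length <- function(x) {
  if (is.matrix(x)) ncol(x) else length(x)
}

series_index <- function(x, idx) {
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
}

is_univariate <- function(x) {
  !is.matrix(x) || nrow(x) == 1L
}

as_vector_series <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 1L) stop("expected a univariate series", call. = FALSE)
    as.numeric(x)
  } else {
    as.numeric(x)
  }
}

check_series <- function(x, name = "x", allow_na = FALSE) {
  if (!is.numeric(x)) stop(sprintf("series '%s' must be numeric", name), call. = FALSE)
  if (series_length(x) < 3L)
    stop(sprintf("series '%s' must have at least 3 time points", name), call. = FALSE)
  if (!allow_na && anyNA(x))
    stop(sprintf("series '%s' contains missing values; apply gap_fill() first", name),
         call. = FALSE)
  invisible(x)
}

check_equal_length <- function(x, y) {
  if (series_length(x) != series_length(y))
    stop("'x' and 'y' must have the same number of time points", call. = FALSE)
  invisible(NULL)
}

#' Fill gaps in a time series
#'
#' Internal gaps (`NA` values) are filled either by linear interpolation
#' between the flanking observed values or by resampling uniformly from the
#' observed values of the same feature. Leading or trailing gaps are not
#' allowed: trim the series to its observed span first.
#'
#' @param s numeric vector, or a features-by-time matrix.
#' @param method `"linear"` (straight-line interpolation) or `"resample"`
#'   (each missing value drawn uniformly from the feature's observed values).
#' @param seed optional integer seed used by the `"resample"` method.
#' @return a series of the same shape with no missing values.
#' @examples
#' gap_fill(c(1, NA, 3))                    # -> 1 2 3
#' gap_fill(c(1, NA, 3), "resample", seed = 1)
#' @export
gap_fill <- function(s, method = c("linear", "resample"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  fill1 <- function(v) {
    obs <- !is.na(v)
    if (!any(obs)) stop("cannot fill an all-missing feature", call. = FALSE)
    if (is.na(v[1L]) || is.na(v[length(v)]))
      stop("leading/trailing gaps must be trimmed before gap filling", call. = FALSE)
    if (all(obs)) return(v)
    if (method == "linear") {
      stats::approx(which(obs), v[obs], xout = seq_along(v))$y
    } else {
      v[!obs] <- sample(v[obs], sum(!obs), replace = TRUE)
      v
    }
  }
  if (is.matrix(s)) t(apply(s, 1L, fill1)) else fill1(s)
}

#' Read time series from a delimited text file
#'
#' Two layouts are supported. `"columns"`: one column per univariate series
#' with a header row of labels (returns a named list of numeric vectors).
#' `"features"`: a feature-by-time table whose first column holds feature IDs
#' (returns a features-by-time numeric matrix with rownames).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` vs `.tsv`/`.txt`) unless `sep` is given.
#' @param layout `"columns"` or `"features"`.
#' @param sep optional field separator overriding the extension-based guess.
#' @return a named list of numeric vectors, or a numeric matrix.
#' @export
read_series <- function(path, layout = c("columns", "features"), sep = NULL) {
  layout <- match.arg(layout)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (layout == "columns") {
    out <- lapply(df, function(col) {
      v <- suppressWarnings(as.numeric(col))
      if (any(is.na(v) & !is.na(col) & col != "" & toupper(col) != "NA"))
        stop("non-numeric cell in series column", call. = FALSE)
      v
    })
    names(out) <- names(df)
    out
  } else {
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
}

#' Write time series to a delimited text file
#'
#' Inverse of [read_series()]: a named list of equal-length vectors is written
#' one series per column; a matrix is written feature-by-time with feature IDs
#' in the first column.
#'
#' @param s named list of numeric vectors, or a features-by-time matrix.
#' @param path output file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_series <- function(s, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.matrix(s)) {
    df <- data.frame(feature = rownames(s), s, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    if (is.numeric(s)) s <- list(series = s)
    df <- as.data.frame(s, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
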