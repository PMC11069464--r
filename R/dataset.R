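#' Build a time-series dataset tibble
#'
#' The canonical container used throughout the package: one row per series,
#' with an `id` column, an integer `label` column (`NA` when unlabelled) and a
#' `value` list-column holding one numeric vector per series. All series must
#' share a common length and contain only finite values.
#'
#' @param values A numeric matrix (one row per series) or a list of equal-length
#'   numeric vectors.
#' @param labels Optional integer class labels, one per series. Labels are kept
#'   for evaluation only; the clustering engines never see them.
#' @param ids Optional character identifiers; generated as `"s1"`, `"s2"`, ...
#'   when missing.
#' @return A tibble with columns `id`, `label`, `value`.
#' @examples
#' ts_dataset(rbind(c(0, 1, 2), c(2, 1, 0)), labels = c(1L, 2L))
#' @export
ts_dataset <- function(values, labels = NULL, ids = NULL) {
  if (is.matrix(values)) {
    values <- lapply(seq_len(nrow(values)), function(i) as.numeric(values[i, ]))
  }
  if (!is.list(values) || length(values) == 0L) {
    stop_empty("`values` must be a non-empty matrix or list of numeric vectors.")
  }
  values <- lapply(values, as.numeric)
  lens <- lengths(values)
  if (length(unique(lens)) != 1L) {
    stop_length("All series must share a common length.")
  }
  if (lens[[1L]] < 1L) stop_length("Series must have length >= 1.")
  if (any(!vapply(values, function(v) all(is.finite(v)), logical(1)))) {
    stop_value("Series values must all be finite.")
  }
  n <- length(values)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  if (length(labels) != n) stop_length("`labels` must have one entry per series.")
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  tibble(id = as.character(ids), label = as.integer(labels), value = values)
}

# Validate a dataset tibble and return it; used at every engine entry point.
check_dataset <- function(data) {
  if (is.matrix(data) || (is.list(data) && !is.data.frame(data))) {
    data <- ts_dataset(data)
  }
  if (!is.data.frame(data) || !all(c("value") %in% names(data))) {
    stop_format("Expected a dataset tibble with a `value` list-column (see ts_dataset()).")
  }
  if (nrow(data) == 0L) stop_empty("Dataset contains no series.")
  lens <- lengths(data$value)
  if (length(unique(lens)) != 1L) stop_length("All series must share a common length.")
  if (any(!vapply(data$value, function(v) all(is.finite(as.numeric(v))), logical(1)))) {
    stop_value("Series values must all be finite.")
  }
  data
}

# m x n matrix of series values, one column per series.
series_matrix <- function(data) {
  vapply(data$value, as.numeric, numeric(length(data$value[[1L]])))
}

#' Total problem size of a dataset
#'
#' The sum of series lengths across the dataset (`n * m` for equal-length
#' series), the scaling covariate used when comparing pruning behaviour
#' across datasets.
#'
#' @param data A dataset tibble.
#' @return A single integer.
#' @export
problem_size <- function(data) {
  data <- check_dataset(data)
  sum(lengths(data$value))
}

#' Read a labelled time-series file in the archive tab-separated dialect
#'
#' Each line is one series: an integer class label in the first field followed
#' by the series values. No header. Files with rows of differing lengths are
#' rejected, mirroring the exclusion of variable-length datasets from fair
#' DTW comparisons.
#'
#' @param path Path to the file.
#' @param sep Field separator; tab by default, use `","` for comma-separated
#'   variants.
#' @return A dataset tibble (see [ts_dataset()]) with labels attached.
#' @export
read_ucr <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_format(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_empty(paste0("Empty dataset file: ", path))
  fields <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(fields)
  if (length(unique(lens)) != 1L) {
    stop_format("Rows have differing lengths; variable-length series are not supported.")
  }
  if (lens[[1L]] < 2L) stop_format("Each row needs a label field plus at least one value.")
  labels <- vapply(fields, function(f) {
    lab <- suppressWarnings(as.numeric(f[[1L]]))
    if (is.na(lab) || lab != round(lab)) {
      stop_format("First field of each row must be an integer class label.")
    }
    as.integer(lab)
  }, integer(1))
  values <- lapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) stop_format("Non-numeric value field in dataset file.")
    v
  })
  ts_dataset(values, labels = labels)
}

#' Write a dataset in the archive tab-separated dialect
#'
#' Inverse of [read_ucr()]: one row per series, integer label first (`0` for
#' unlabelled series), then the values. Values are printed with 17 significant
#' digits so that a write/read round trip is bit-identical.
#'
#' @param data A dataset tibble.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ucr <- function(data, path, sep = "\t") {
  data <- check_dataset(data)
  labels <- if ("label" %in% names(data)) data$label else rep(NA_integer_, nrow(data))
  labels[is.na(labels)] <- 0L
  lines <- vapply(seq_len(nrow(data)), function(i) {
    paste(c(as.character(labels[[i]]),
            sprintf("%.17g", as.numeric(data$value[[i]]))),
          collapse = sep)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
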