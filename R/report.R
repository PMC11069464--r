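#' Run a clustering engine and assemble a run report
#'
#' Dispatches to the SOM or k-means engine, evaluates the six agreement
#' indices against the dataset's stored labels when they exist (labels are
#' never visible to the engines themselves), and collects the pruning
#' instrumentation: total DTW calls, total candidate comparisons and the
#' pruning fraction `1 - dtw_calls / comparisons`. With
#' `compare_pruning = TRUE` the run is repeated with pruning disabled and the
#' label agreement recorded (identical by construction).
#'
#' @param data Dataset tibble.
#' @param algorithm `"som"` or `"kmeans"`.
#' @param k Number of classes/clusters (SOM classification mode lays the mesh
#'   out as `1 x k`). For a visualisation mesh, pass `rows`/`cols` instead
#'   through `...`.
#' @param seed Integer seed.
#' @param pruning Use bound pruning.
#' @param compare_pruning Also run without pruning and compare labels.
#' @param ... Passed to [train_som()] or [dtw_kmeans()] (`epochs`,
#'   `iterations`, `window_fraction`, `rows`, `cols`, ...).
#' @return A list of class `warp_report`: `algorithm`, `config`, `labels`,
#'   `metrics` (one-row tibble or `NULL`), `stats` (per-epoch/iteration
#'   pruning log), `total_dtw_calls`, `total_comparisons`,
#'   `pruning_fraction`, `fit`, and optionally `pruning_comparison`.
#' @export
run_cluster <- function(data, algorithm = c("som", "kmeans"), k = NULL,
                        seed = 1L, pruning = TRUE, compare_pruning = FALSE, ...) {
  algorithm <- match.arg(algorithm)
  data <- check_dataset(data)

  run_one <- function(prune) {
    if (algorithm == "som") {
      fit <- train_som(data, k = k, pruning = prune, seed = seed, ...)
      list(fit = fit, labels = predict(fit, data, pruning = prune),
           stats = fit$epoch_log)
    } else {
      if (is.null(k)) stop_parameter("`k` is required for the k-means engine.")
      fit <- dtw_kmeans(data, k = k, pruning = prune, seed = seed, ...)
      list(fit = fit, labels = fit$labels, stats = fit$iter_log)
    }
  }

  main <- run_one(pruning)
  total_dtw <- sum(main$stats$n_dtw_calls)
  total_cand <- sum(main$stats$n_candidates)

  metrics <- NULL
  if ("label" %in% names(data) && !anyNA(data$label)) {
    metrics <- cluster_metrics(data$label, main$labels)
  }

  report <- structure(list(
    algorithm = algorithm,
    config = c(list(k = k, seed = seed, pruning = pruning), list(...)),
    dataset_name = attr(data, "name"),
    n = nrow(data), m = length(data$value[[1L]]),
    problem_size = problem_size(data),
    labels = main$labels,
    metrics = metrics,
    stats = main$stats,
    total_dtw_calls = total_dtw,
    total_comparisons = total_cand,
    pruning_fraction = 1 - total_dtw / total_cand,
    fit = main$fit
  ), class = "warp_report")

  if (compare_pruning) {
    other <- run_one(!pruning)
    report$pruning_comparison <- list(
      labels_identical = identical(as.integer(main$labels),
                                   as.integer(other$labels)),
      dtw_calls_with = if (pruning) total_dtw else sum(other$stats$n_dtw_calls),
      dtw_calls_without = if (pruning) sum(other$stats$n_dtw_calls) else total_dtw
    )
  }
  report
}

#' Write a run report as structured text (JSON)
#'
#' @param report A `warp_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "warp_report")) stop_parameter("`report` must be a warp_report.")
  doc <- report[setdiff(names(report), "fit")]
  doc$labels <- as.integer(doc$labels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @export
print.warp_report <- function(x, ...) {
  cat(sprintf("warpclust run: %s on %d series (length %d, problem size %d)\n",
              x$algorithm, x$n, x$m, x$problem_size))
  cat(sprintf("DTW calls: %d of %d comparisons (pruning fraction %.3f)\n",
              x$total_dtw_calls, x$total_comparisons, x$pruning_fraction))
  if (!is.null(x$metrics)) {
    cat("Agreement with stored labels:\n")
    print(as.data.frame(x$metrics), row.names = FALSE)
  }
  if (!is.null(x$pruning_comparison)) {
    cat(sprintf("Pruned vs unpruned labels identical: %s (DTW calls %d vs %d)\n",
                x$pruning_comparison$labels_identical,
                x$pruning_comparison$dtw_calls_with,
                x$pruning_comparison$dtw_calls_without))
  }
  invisible(x)
}
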