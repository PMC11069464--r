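#' Tidy a trained SOM: one row per node
#'
#' @param x A `warp_som`.
#' @param ... Unused.
#' @return A tibble with `node`, `row`, `col`, the node weight series as a
#'   list-column `weight`, and the U-matrix `umatrix` value.
#' @export
tidy.warp_som <- function(x, ...) {
  um <- som_umatrix(x)
  tibble(
    node = um$node, row = um$row, col = um$col,
    weight = lapply(um$node, function(j) x$weights[, j]),
    umatrix = um$value
  )
}

#' One-row summary of a trained SOM
#'
#' @param x A `warp_som`.
#' @param ... Unused.
#' @return A one-row tibble with mesh layout, training configuration, total
#'   DTW calls, total candidate comparisons and the pruning fraction.
#' @export
glance.warp_som <- function(x, ...) {
  total_dtw <- if (!is.null(x$epoch_log)) sum(x$epoch_log$n_dtw_calls) else NA_real_
  total_cand <- if (!is.null(x$epoch_log)) sum(x$epoch_log$n_candidates) else NA_real_
  tibble(
    rows = x$rows, cols = x$cols, toroidal = x$toroidal,
    n = x$n, m = x$m, epochs = x$epochs, window = x$window,
    pruning = isTRUE(x$pruning),
    total_dtw_calls = total_dtw, total_comparisons = total_cand,
    pruning_fraction = 1 - total_dtw / total_cand
  )
}

#' Augment a dataset with SOM assignments
#'
#' @param x A trained `warp_som`.
#' @param data The dataset tibble to assign.
#' @param ... Unused.
#' @return `data` with `.bmu` (flat node index) and `.distance` (DTW distance
#'   to the BMU weight) columns appended.
#' @export
augment.warp_som <- function(x, data, ...) {
  data <- check_dataset(data)
  X <- series_matrix(data)
  res <- lapply(seq_len(ncol(X)), function(i) {
    best_match_impl(X[, i], x$weights, x$window, pruning = TRUE,
                    envelope = dtw_envelope(X[, i], x$window))
  })
  data$.bmu <- vapply(res, `[[`, integer(1), "index")
  data$.distance <- vapply(res, `[[`, numeric(1), "distance")
  data
}

#' U-matrix heat map of a trained SOM
#'
#' @param object A trained `warp_som`.
#' @param ... Unused.
#' @return A ggplot: mesh tiles shaded by mean DTW distance to neighbouring
#'   nodes; light ridges separate clusters of nodes.
#' @export
autoplot.warp_som <- function(object, ...) {
  um <- som_umatrix(object)
  ggplot2::ggplot(um, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "mean DTW\nto neighbours",
                  title = "U-matrix") +
    ggplot2::theme_minimal()
}

#' Tidy a DTW k-means fit: one row per cluster
#'
#' @param x A `warp_kmeans`.
#' @param ... Unused.
#' @return A tibble with `cluster`, `size`, the centroid as a list-column and
#'   the mean DTW distance of members to it.
#' @export
tidy.warp_kmeans <- function(x, ...) {
  tibble(
    cluster = seq_len(x$k),
    size = vapply(seq_len(x$k), function(j) sum(x$labels == j), integer(1)),
    centroid = lapply(seq_len(x$k), function(j) x$centroids[, j]),
    mean_dtw = vapply(seq_len(x$k), function(j) {
      member <- x$labels == j
      if (any(member)) mean(x$distances[member]) else NA_real_
    }, numeric(1))
  )
}

#' One-row summary of a DTW k-means fit
#'
#' @param x A `warp_kmeans`.
#' @param ... Unused.
#' @return A one-row tibble with `k`, sizes of the run, convergence flag,
#'   total DTW calls and pruning fraction.
#' @export
glance.warp_kmeans <- function(x, ...) {
  tibble(
    k = x$k, n = x$n, m = x$m,
    iterations = x$iterations_run, converged = x$converged,
    window = x$window, pruning = isTRUE(x$pruning),
    total_dtw_calls = sum(x$iter_log$n_dtw_calls),
    total_comparisons = sum(x$iter_log$n_candidates),
    pruning_fraction = 1 - sum(x$iter_log$n_dtw_calls) / sum(x$iter_log$n_candidates)
  )
}

#' Augment a dataset with k-means assignments
#'
#' @param x A `warp_kmeans`.
#' @param data The dataset tibble to assign.
#' @param ... Unused.
#' @return `data` with `.cluster` and `.distance` columns appended.
#' @export
augment.warp_kmeans <- function(x, data, ...) {
  data <- check_dataset(data)
  asg <- assign_step(data, x$centroids, x$window)
  data$.cluster <- asg$labels
  data$.distance <- asg$distances
  data
}

#' Cluster profile plot of a DTW k-means fit
#'
#' @param object A `warp_kmeans`.
#' @param data Optional dataset tibble; when supplied, member series are drawn
#'   behind the centroids.
#' @param ... Unused.
#' @return A ggplot faceted by cluster: member series in grey, centroid in
#'   colour.
#' @export
autoplot.warp_kmeans <- function(object, data = NULL, ...) {
  cent <- tidy(object) |>
    dplyr::mutate(series = "centroid") |>
    tidyr::unnest_longer("centroid", values_to = "value", indices_to = "time")
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time, y = .data$value))
  if (!is.null(data)) {
    aug <- augment(object, data) |>
      dplyr::mutate(cluster = .data$.cluster) |>
      tidyr::unnest_longer("value", values_to = "value", indices_to = "time")
    p <- p + ggplot2::geom_line(
      data = aug,
      mapping = ggplot2::aes(group = .data$id),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(data = cent,
                       ggplot2::aes(colour = factor(.data$cluster)),
                       linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time", y = "value", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot the series of a dataset tibble
#'
#' @param data A dataset tibble.
#' @param colour_by Column to colour lines by (default `label`).
#' @return A ggplot of all series overlaid.
#' @export
plot_series <- function(data, colour_by = "label") {
  data <- check_dataset(data)
  long <- tidyr::unnest_longer(data, "value", values_to = "value",
                               indices_to = "time")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     group = .data$id,
                                     colour = factor(.data[[colour_by]]))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time", y = "value", colour = colour_by) +
    ggplot2::theme_minimal()
}
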