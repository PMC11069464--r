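#' K-means clustering of time series under DTW with exact bound pruning
#'
#' Lloyd-style alternation: observations are assigned to their DTW-nearest
#' centroid, then each centroid is replaced by the pointwise mean of its
#' members. Assignment uses the same two-step pruning as the SOM engine — the
#' minimum Euclidean distance to the centroids is the threshold and centroids
#' whose LB_Keogh lower bound exceeds it are skipped — which cannot change any
#' assignment because a pruned centroid provably is not the nearest. Iteration
#' stops when the labelling repeats or after `iterations` rounds.
#'
#' @param data Dataset tibble (see [ts_dataset()]), matrix or list of series.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param iterations Maximum assign/update rounds (default 10).
#' @param window_fraction DTW window as a fraction of series length.
#' @param pruning Use bound pruning (labels and centroids are identical either
#'   way).
#' @param seed Integer seed for centroid initialisation.
#' @return An object of class `warp_kmeans` with `labels` (integer, 1..k),
#'   `centroids` (m x k matrix), `distances` (DTW distance of each observation
#'   to its centroid), per-iteration pruning counters in `$iter_log`, and
#'   `converged`.
#' @examples
#' d <- synth_dataset(n_classes = 2, per_class = 5, length = 30, seed = 1)
#' km <- dtw_kmeans(d, k = 2, seed = 1)
#' table(d$label, km$labels)
#' @export
dtw_kmeans <- function(data, k, iterations = 10, window_fraction = 0.05,
                       pruning = TRUE, seed = 1L) {
  data <- check_dataset(data)
  X <- series_matrix(data)
  n <- ncol(X)
  m <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) stop_parameter("`k` must satisfy 1 <= k <= n.")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop_parameter("`iterations` must be >= 1.")
  window <- dtw_window(m, window_fraction)

  centroids <- init_centroids(data, k, seed = seed)
  envs <- if (pruning) lapply(seq_len(n), function(i) dtw_envelope(X[, i], window))

  labels <- rep(NA_integer_, n)
  log_rows <- list()
  converged <- FALSE
  iters_run <- 0L
  for (it in seq_len(iterations)) {
    iters_run <- it
    asg <- assign_impl(X, centroids, window, pruning, envs)
    log_rows[[it]] <- c(iteration = it, asg$stats)
    if (!anyNA(labels) && all(asg$labels == labels)) {
      labels <- asg$labels
      converged <- TRUE
      break
    }
    labels <- asg$labels
    centroids <- update_centroids(data, labels, k,
                                  distances = asg$distances,
                                  window = window)
  }
  iter_log <- as_tibble(as.data.frame(do.call(rbind, log_rows)))

  final <- assign_impl(X, centroids, window, pruning, envs)
  structure(list(
    labels = final$labels, centroids = centroids, distances = final$distances,
    k = k, m = m, n = n, window = window, window_fraction = window_fraction,
    iterations = iterations, iterations_run = iters_run,
    converged = converged, pruning = pruning, seed = as.integer(seed),
    iter_log = iter_log
  ), class = "warp_kmeans")
}

#' Seeded centroid initialisation
#'
#' Draws `k` distinct dataset members (without replacement) as the starting
#' centroids; reproducible for a fixed seed.
#'
#' @param data Dataset tibble / matrix / list of series.
#' @param k Number of centroids, `k <= n`.
#' @param seed Integer seed.
#' @return An m x k matrix, one centroid per column.
#' @export
init_centroids <- function(data, k, seed = 1L) {
  data <- check_dataset(data)
  X <- series_matrix(data)
  k <- as.integer(k)
  if (k > ncol(X)) stop_parameter("`k` cannot exceed the number of series.")
  if (k < 1L) stop_parameter("`k` must be >= 1.")
  withr::local_seed(as.integer(seed))
  X[, sample.int(ncol(X), k, replace = FALSE), drop = FALSE]
}

# One assignment sweep: pruned-but-exact nearest-centroid search per
# observation, counters accumulated over the sweep.
assign_impl <- function(X, centroids, window, pruning, envs = NULL) {
  n <- ncol(X)
  labels <- integer(n)
  dists <- numeric(n)
  counters <- c(n_candidates = 0L, n_upper_bound_evals = 0L,
                n_lower_bound_evals = 0L, n_dtw_calls = 0L, n_pruned = 0L)
  for (i in seq_len(n)) {
    bm <- best_match_impl(X[, i], centroids, window, pruning = pruning,
                          envelope = if (pruning) envs[[i]])
    labels[i] <- bm$index
    dists[i] <- bm$distance
    counters <- counters + bm$stats
  }
  list(labels = labels, distances = dists, stats = counters)
}

#' Assign observations to their DTW-nearest centroid
#'
#' @param data Dataset tibble / matrix / list of series.
#' @param centroids An m x k matrix (or list of series) of centroids.
#' @param window Integer DTW window.
#' @param pruning Use bound pruning; assignments are identical either way.
#' @return A list with `labels` (1..k), `distances` and `stats` (the summed
#'   pruning counters of the sweep).
#' @export
assign_step <- function(data, centroids, window, pruning = TRUE) {
  data <- check_dataset(data)
  X <- series_matrix(data)
  centroids <- candidate_matrix(centroids, nrow(X))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_parameter("`window` must be an integer >= 1.")
  envs <- if (pruning) {
    lapply(seq_len(ncol(X)), function(i) dtw_envelope(X[, i], window))
  }
  assign_impl(X, centroids, window, pruning, envs)
}

#' Recompute centroids as pointwise cluster means
#'
#' Centroid `j` becomes the arithmetic mean, per time step, of the series
#' assigned to cluster `j` (well-defined because all series share a length).
#' A cluster left empty is re-seeded with the observation farthest (by DTW)
#' from its own centroid, so `k` centroids are always returned.
#'
#' @param data Dataset tibble / matrix / list of series.
#' @param labels Integer cluster labels in `1..k`, one per observation.
#' @param k Number of clusters.
#' @param distances Optional DTW distances of each observation to its assigned
#'   centroid (used to pick the re-seeding observation for empty clusters);
#'   recomputed if missing.
#' @param window DTW window used only when `distances` must be recomputed.
#' @return An m x k matrix of centroids.
#' @export
update_centroids <- function(data, labels, k, distances = NULL, window = NULL) {
  data <- check_dataset(data)
  X <- series_matrix(data)
  k <- as.integer(k)
  labels <- as.integer(labels)
  if (length(labels) != ncol(X)) stop_length("One label per observation required.")
  if (any(labels < 1L | labels > k)) stop_parameter("Labels must lie in 1..k.")
  centroids <- matrix(NA_real_, nrow = nrow(X), ncol = k)
  for (j in seq_len(k)) {
    members <- which(labels == j)
    if (length(members) > 0L) {
      centroids[, j] <- rowMeans(X[, members, drop = FALSE])
    }
  }
  empty <- which(colSums(is.na(centroids)) > 0L)
  if (length(empty) > 0L) {
    if (is.null(distances)) {
      if (is.null(window)) window <- dtw_window(nrow(X), 0.05)
      distances <- vapply(seq_len(ncol(X)), function(i) {
        .dtw_cpp(X[, i], centroids[, labels[i]], as.integer(window))
      }, numeric(1))
    }
    used <- integer(0)
    for (j in empty) {
      ord <- order(distances, decreasing = TRUE)
      pick <- ord[!(ord %in% used)][1L]
      centroids[, j] <- X[, pick]
      used <- c(used, pick)
    }
  }
  centroids
}

#' Write cluster assignments as a comma-separated table
#'
#' Two columns, `id` and `label`, one row per series.
#'
#' @param data The clustered dataset tibble (for the ids).
#' @param labels Integer labels, one per series.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(data, labels, path) {
  data <- check_dataset(data)
  if (length(labels) != nrow(data)) stop_length("One label per series required.")
  utils::write.csv(data.frame(id = data$id, label = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.warp_kmeans <- function(x, ...) {
  cat(sprintf("DTW k-means: k = %d, %d series of length %d\n", x$k, x$n, x$m))
  cat(sprintf("%d/%d iterations%s; DTW calls %d of %d comparisons (%.1f%% pruned)\n",
              x$iterations_run, x$iterations,
              if (x$converged) " (converged)" else "",
              sum(x$iter_log$n_dtw_calls), sum(x$iter_log$n_candidates),
              100 * (1 - sum(x$iter_log$n_dtw_calls) / sum(x$iter_log$n_candidates))))
  invisible(x)
}
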