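#' Self-organizing map clustering of time series under DTW
#'
#' Trains a 2-D Kohonen map whose node weights are themselves time series.
#' Every observation is compared to every node weight with the windowed DTW
#' distance; the nearest node (the best matching unit, BMU) and its grid
#' neighbourhood are pulled toward the observation, with both the learning
#' rate and the neighbourhood radius decaying linearly over epochs. BMU
#' searches use exact Euclidean/LB_Keogh bound pruning, so the trained map is
#' bit-identical with pruning on or off; pruning only reduces the number of
#' full DTW evaluations, which is logged per epoch.
#'
#' With `k` supplied (classification mode) the mesh is laid out as a single
#' row of `k` nodes and BMU indices serve directly as class assignments.
#'
#' @param data A dataset tibble (see [ts_dataset()]), matrix or list of series.
#' @param rows,cols Mesh dimensions; ignored when `k` is given.
#' @param k Classification mode: lay out `1 x k` nodes, one per expected class.
#' @param epochs Number of passes over the data (default 100).
#' @param alpha Initial learning rate in `(0, 1]`.
#' @param radius Initial neighbourhood radius; defaults to
#'   `max(rows, cols) / 2`.
#' @param toroidal Wrap the mesh edges (default `TRUE`).
#' @param window_fraction DTW window as a fraction of series length
#'   (default 0.05).
#' @param pruning Use bound pruning in BMU searches (results are identical
#'   either way).
#' @param seed Integer seed controlling initialisation and per-epoch visit
#'   order.
#' @return An object of class `warp_som`: trained weights, mesh layout, the
#'   per-epoch log of learning rate, radius and pruning counters
#'   (`$epoch_log`), and the BMU trajectory (`$bmu_log`, epochs x n).
#' @seealso [predict.warp_som()], [som_umatrix()], [tidy.warp_som()]
#' @examples
#' d <- synth_dataset(n_classes = 2, per_class = 5, length = 30, seed = 1)
#' fit <- train_som(d, k = 2, epochs = 10, seed = 1)
#' table(d$label, predict(fit, d))
#' @export
train_som <- function(data, rows = 3, cols = 3, k = NULL, epochs = 100,
                      alpha = 0.9, radius = NULL, toroidal = TRUE,
                      window_fraction = 0.05, pruning = TRUE, seed = 1L) {
  data <- check_dataset(data)
  if (!is.null(k)) {
    rows <- 1L
    cols <- as.integer(k)
  }
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop_parameter("Mesh dimensions must be >= 1.")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop_parameter("`epochs` must be >= 1.")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop_parameter("`alpha` must lie in (0, 1].")
  }
  if (is.null(radius)) radius <- max(rows, cols) / 2
  if (!is.finite(radius) || radius <= 0) stop_parameter("`radius` must be > 0.")

  X <- series_matrix(data)
  m <- nrow(X)
  n <- ncol(X)
  window <- dtw_window(m, window_fraction)
  M <- rows * cols
  d2 <- grid_dist2(rows, cols, toroidal)

  withr::local_seed(as.integer(seed))
  Wmat <- X[, sample.int(n, M, replace = TRUE), drop = FALSE]
  init_weights <- Wmat

  envs <- if (pruning) lapply(seq_len(n), function(i) dtw_envelope(X[, i], window))

  log_rows <- vector("list", epochs)
  bmu_log <- matrix(0L, nrow = epochs, ncol = n)
  for (e in seq_len(epochs) - 1L) {
    sched <- decay_schedule(e, epochs, alpha, radius)
    lr <- sched$learning_rate
    rad <- sched$radius
    counters <- c(n_candidates = 0L, n_upper_bound_evals = 0L,
                  n_lower_bound_evals = 0L, n_dtw_calls = 0L, n_pruned = 0L)
    for (i in sample.int(n)) {
      bm <- best_match_impl(X[, i], Wmat, window, pruning = pruning,
                            envelope = if (pruning) envs[[i]])
      counters <- counters + bm$stats
      bmu_log[e + 1L, i] <- bm$index
      Wmat <- kernel_update(Wmat, d2[, bm$index], X[, i], lr, rad)
    }
    log_rows[[e + 1L]] <- c(epoch = e + 1L, learning_rate = lr, radius = rad,
                            counters)
  }
  epoch_log <- as_tibble(as.data.frame(do.call(rbind, log_rows)))

  structure(list(
    weights = Wmat, init_weights = init_weights,
    rows = rows, cols = cols, toroidal = toroidal,
    m = m, n = n, window = window, window_fraction = window_fraction,
    epochs = epochs, alpha = alpha, radius = radius,
    pruning = pruning, seed = as.integer(seed),
    epoch_log = epoch_log, bmu_log = bmu_log
  ), class = "warp_som")
}

#' Initialise a self-organizing map from data
#'
#' Each node weight is a copy of a uniformly sampled dataset member, so
#' weights start inside the data range and DTW windows are meaningful from
#' the first epoch. Reproducible for a fixed seed; [train_som()] performs the
#' identical initialisation for the same seed.
#'
#' @inheritParams train_som
#' @return An untrained `warp_som` object (zero epochs run).
#' @export
init_som <- function(data, rows = 3, cols = 3, k = NULL, toroidal = TRUE,
                     window_fraction = 0.05, seed = 1L) {
  data <- check_dataset(data)
  if (!is.null(k)) {
    rows <- 1L
    cols <- as.integer(k)
  }
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop_parameter("Mesh dimensions must be >= 1.")
  X <- series_matrix(data)
  m <- nrow(X)
  n <- ncol(X)
  withr::local_seed(as.integer(seed))
  Wmat <- X[, sample.int(n, rows * cols, replace = TRUE), drop = FALSE]
  structure(list(
    weights = Wmat, init_weights = Wmat,
    rows = rows, cols = cols, toroidal = toroidal,
    m = m, n = n, window = dtw_window(m, window_fraction),
    window_fraction = window_fraction,
    epochs = 0L, alpha = NA_real_, radius = NA_real_,
    pruning = NA, seed = as.integer(seed),
    epoch_log = NULL, bmu_log = NULL
  ), class = "warp_som")
}

#' Linear decay schedule for learning rate and neighbourhood radius
#'
#' At epoch `t` (0-based) of `E`: `alpha_t = alpha0 * (1 - t / E)` and
#' `r_t = max(1, r0 * (1 - t / E))`; both are non-increasing in `t`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param epochs Total number of epochs `E`.
#' @param alpha Initial learning rate.
#' @param radius Initial radius.
#' @return List with `learning_rate` and `radius`.
#' @export
decay_schedule <- function(epoch, epochs, alpha = 0.9, radius = 1) {
  if (epoch < 0 || epoch >= epochs) {
    stop_parameter("`epoch` must satisfy 0 <= epoch < epochs.")
  }
  frac <- 1 - epoch / epochs
  list(learning_rate = alpha * frac, radius = max(1, radius * frac))
}

# Squared grid distances between all node pairs; row-major flat indexing
# (node j sits at row (j-1) %/% cols + 1, column (j-1) %% cols + 1).
grid_dist2 <- function(rows, cols, toroidal) {
  pos <- cbind(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
  M <- rows * cols
  d2 <- matrix(0, M, M)
  for (a in seq_len(M)) {
    dr <- abs(pos[, 1] - pos[a, 1])
    dc <- abs(pos[, 2] - pos[a, 2])
    if (toroidal) {
      dr <- pmin(dr, rows - dr)
      dc <- pmin(dc, cols - dc)
    }
    d2[, a] <- dr^2 + dc^2
  }
  d2
}

# Gaussian-kernel pull of all node weights toward x. d2col is the column of
# squared grid distances to the BMU. A radius of (or near) zero collapses the
# kernel onto the BMU alone.
kernel_update <- function(Wmat, d2col, x, lr, radius) {
  h <- if (radius <= 1e-12) as.numeric(d2col == 0) else exp(-d2col / (2 * radius^2))
  Wmat + (x - Wmat) * rep(lr * h, each = nrow(Wmat))
}

#' Neighbourhood update of SOM weights
#'
#' Pulls every node weight toward the query, scaled by the learning rate and
#' a Gaussian kernel `h(d) = exp(-d^2 / (2 * radius^2))` of the grid distance
#' `d` to the BMU (toroidal distance when the mesh wraps). Each weight moves
#' as `w_i <- w_i + lr * h(d) * (x_i - w_i)`, a convex combination that keeps
#' weights inside the pointwise range of data and current weights.
#'
#' @param som A `warp_som` object.
#' @param bmu Flat (row-major, 1-based) index of the best matching unit.
#' @param query Numeric vector of the observation.
#' @param learning_rate Learning rate in `[0, 1]`.
#' @param radius Neighbourhood radius (>= 0).
#' @return The `warp_som` with updated weights.
#' @export
update_weights <- function(som, bmu, query, learning_rate, radius) {
  if (!inherits(som, "warp_som")) stop_parameter("`som` must be a warp_som object.")
  if (learning_rate < 0 || learning_rate > 1) {
    stop_parameter("`learning_rate` must lie in [0, 1].")
  }
  if (radius < 0) stop_parameter("`radius` must be >= 0.")
  query <- as.numeric(query)
  if (length(query) != som$m) stop_length("Query length must match node weights.")
  d2 <- grid_dist2(som$rows, som$cols, som$toroidal)
  som$weights <- kernel_update(som$weights, d2[, bmu], query, learning_rate, radius)
  som
}

#' Assign observations to map nodes
#'
#' Each observation's label is the flat (row-major, 1-based) index of its best
#' matching unit, found with the same pruned-but-exact DTW search used in
#' training. In classification mode (`1 x k` mesh) these indices are the class
#' assignments.
#'
#' @param object A trained `warp_som`.
#' @param data Dataset tibble / matrix / list of series to assign.
#' @param pruning Use bound pruning (assignments are identical either way).
#' @param ... Unused.
#' @return Integer vector of node indices, one per observation.
#' @export
predict.warp_som <- function(object, data, pruning = TRUE, ...) {
  data <- check_dataset(data)
  X <- series_matrix(data)
  if (nrow(X) != object$m) stop_length("Series length does not match the trained map.")
  vapply(seq_len(ncol(X)), function(i) {
    best_match_impl(X[, i], object$weights, object$window, pruning = pruning)$index
  }, integer(1))
}

# 4-neighbourhood of a node on the mesh (wrapping when toroidal); self and
# out-of-range neighbours dropped.
node_neighbors <- function(r, c, rows, cols, toroidal) {
  cand <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  if (toroidal) {
    cand[, 1] <- (cand[, 1] - 1L) %% rows + 1L
    cand[, 2] <- (cand[, 2] - 1L) %% cols + 1L
  }
  keep <- cand[, 1] >= 1 & cand[, 1] <= rows & cand[, 2] >= 1 & cand[, 2] <= cols &
    !(cand[, 1] == r & cand[, 2] == c)
  cand <- cand[keep, , drop = FALSE]
  unique((cand[, 1] - 1L) * cols + cand[, 2])
}

#' Unified distance matrix (U-matrix) of a trained map
#'
#' For every node, the mean windowed DTW distance between its weight series
#' and the weights of its 4-neighbours on the mesh (wrapping when toroidal).
#' Large values trace cluster boundaries on the organised map.
#'
#' @param som A trained `warp_som`.
#' @param window DTW window; defaults to the window used in training.
#' @return A tibble with columns `row`, `col`, `node`, `value`.
#' @export
som_umatrix <- function(som, window = NULL) {
  if (!inherits(som, "warp_som")) stop_parameter("`som` must be a warp_som object.")
  if (is.null(window)) window <- som$window
  rows <- som$rows
  cols <- som$cols
  vals <- numeric(rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      j <- (r - 1L) * cols + c
      nb <- node_neighbors(r, c, rows, cols, som$toroidal)
      vals[j] <- if (length(nb) == 0L) 0 else {
        mean(vapply(nb, function(b) {
          .dtw_cpp(som$weights[, j], som$weights[, b], as.integer(window))
        }, numeric(1)))
      }
    }
  }
  tibble(row = rep(seq_len(rows), each = cols),
         col = rep(seq_len(cols), rows),
         node = seq_len(rows * cols),
         value = vals)
}

#' Write a U-matrix as a tab-separated grid
#'
#' @param som A trained `warp_som`.
#' @param path Output path.
#' @param window DTW window; defaults to the training window.
#' @return `path`, invisibly.
#' @export
write_umatrix <- function(som, path, window = NULL) {
  um <- som_umatrix(som, window = window)
  mat <- matrix(um$value, nrow = som$rows, ncol = som$cols, byrow = TRUE)
  utils::write.table(mat, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a trained map as a structured text document
#'
#' Serialises mesh layout, training configuration, node weights and the epoch
#' log to JSON so a trained map can be archived or re-loaded with
#' [read_som()].
#'
#' @param som A `warp_som` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_som <- function(som, path) {
  if (!inherits(som, "warp_som")) stop_parameter("`som` must be a warp_som object.")
  doc <- list(
    rows = som$rows, cols = som$cols, toroidal = som$toroidal,
    m = som$m, n = som$n, window = som$window,
    window_fraction = som$window_fraction, epochs = som$epochs,
    alpha = som$alpha, radius = som$radius, pruning = som$pruning,
    seed = som$seed,
    weights = lapply(seq_len(ncol(som$weights)), function(j) som$weights[, j]),
    epoch_log = som$epoch_log
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Re-load a trained map written by [write_som()]
#'
#' @param path Path to the JSON document.
#' @return A `warp_som` object.
#' @export
read_som <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- if (is.list(doc$weights)) {
    vapply(doc$weights, as.numeric, numeric(doc$m))
  } else {
    matrix(as.numeric(t(doc$weights)), nrow = doc$m)
  }
  structure(list(
    weights = weights, init_weights = NULL,
    rows = as.integer(doc$rows), cols = as.integer(doc$cols),
    toroidal = as.logical(doc$toroidal),
    m = as.integer(doc$m), n = as.integer(doc$n),
    window = as.integer(doc$window), window_fraction = doc$window_fraction,
    epochs = as.integer(doc$epochs), alpha = doc$alpha, radius = doc$radius,
    pruning = doc$pruning, seed = as.integer(doc$seed),
    epoch_log = if (!is.null(doc$epoch_log)) as_tibble(doc$epoch_log),
    bmu_log = NULL
  ), class = "warp_som")
}

#' @export
print.warp_som <- function(x, ...) {
  cat(sprintf("DTW self-organizing map: %d x %d mesh%s, series length %d\n",
              x$rows, x$cols, if (x$toroidal) " (toroidal)" else "", x$m))
  if (x$epochs > 0L && !is.null(x$epoch_log)) {
    total <- sum(x$epoch_log$n_dtw_calls)
    cand <- sum(x$epoch_log$n_candidates)
    cat(sprintf("Trained %d epochs on %d series; DTW calls %d of %d (%.1f%% pruned)\n",
                x$epochs, x$n, total, cand, 100 * (1 - total / cand)))
  } else {
    cat("Untrained (initialised only)\n")
  }
  invisible(x)
}
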