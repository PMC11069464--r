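#' Pruning threshold for a best-match search
#'
#' The Euclidean (upper-bound) distance from the query to every candidate is
#' computed and the minimum taken. Any candidate whose LB_Keogh lower bound
#' exceeds this threshold cannot be the DTW-nearest candidate, so the full
#' DTW computation for it can be skipped without changing the answer.
#'
#' @param query Numeric vector.
#' @param candidates A list of equal-length numeric vectors, a matrix with one
#'   candidate per column, or a dataset tibble.
#' @return The minimum Euclidean distance (a non-negative scalar).
#' @export
prune_threshold <- function(query, candidates) {
  query <- as.numeric(query)
  cand <- candidate_matrix(candidates, length(query))
  min(sqrt(colSums((cand - query)^2)))
}

# Coerce candidates (list / matrix / dataset tibble) to an m x n matrix.
candidate_matrix <- function(candidates, m) {
  if (is.data.frame(candidates)) candidates <- candidates$value
  if (is.list(candidates)) {
    if (length(candidates) == 0L) stop_empty("Candidate list is empty.")
    lens <- lengths(candidates)
    if (any(lens != m)) stop_length("Candidates must match the query length.")
    candidates <- vapply(candidates, as.numeric, numeric(m))
  }
  if (!is.matrix(candidates)) candidates <- matrix(as.numeric(candidates), nrow = m)
  if (ncol(candidates) == 0L) stop_empty("Candidate list is empty.")
  if (nrow(candidates) != m) stop_length("Candidates must match the query length.")
  candidates
}

# Core two-step pruned search over a candidate matrix (m x n). Returns the
# exact DTW argmin with bound-evaluation counters. No RNG is consumed, so
# toggling `pruning` can never alter a seeded caller's trajectory.
best_match_impl <- function(query, cand, window, pruning = TRUE, envelope = NULL) {
  n <- ncol(cand)
  if (pruning) {
    ed <- sqrt(colSums((cand - query)^2))
    threshold <- min(ed)
    if (is.null(envelope)) envelope <- dtw_envelope(query, window)
    # Strictly-greater prune test; the epsilon absorbs round-off when a
    # candidate's lower bound mathematically equals the threshold (e.g. a
    # zero-width envelope), where summation order can differ by a few ulps.
    # Keeping such boundary candidates can only add DTW calls, never change
    # the argmin.
    prune_at <- threshold + 1e-9 * (1 + threshold)
    best_i <- 0L
    best_d <- Inf
    n_dtw <- 0L
    for (j in seq_len(n)) {
      lb <- .lb_keogh_cpp(cand[, j], envelope$upper, envelope$lower)
      if (lb > prune_at) next
      d <- .dtw_cpp(query, cand[, j], window)
      n_dtw <- n_dtw + 1L
      if (d < best_d) {
        best_d <- d
        best_i <- j
      }
    }
    list(index = best_i, distance = best_d,
         stats = c(n_candidates = n, n_upper_bound_evals = n,
                   n_lower_bound_evals = n, n_dtw_calls = n_dtw,
                   n_pruned = n - n_dtw))
  } else {
    best_i <- 0L
    best_d <- Inf
    for (j in seq_len(n)) {
      d <- .dtw_cpp(query, cand[, j], window)
      if (d < best_d) {
        best_d <- d
        best_i <- j
      }
    }
    list(index = best_i, distance = best_d,
         stats = c(n_candidates = n, n_upper_bound_evals = 0L,
                   n_lower_bound_evals = 0L, n_dtw_calls = n,
                   n_pruned = 0L))
  }
}

#' Find the DTW-nearest candidate with exact bound pruning
#'
#' Two-step search: the minimum Euclidean distance over candidates sets the
#' pruning threshold; candidates whose LB_Keogh lower bound exceeds it are
#' excluded; the full windowed DTW is computed only for the survivors (the
#' qualification region). The returned index and distance are identical to a
#' brute-force DTW argmin — pruning only removes work, never changes the
#' answer. Ties are broken toward the lowest candidate index.
#'
#' @param query Numeric vector.
#' @param candidates List / matrix (one candidate per column) / dataset tibble.
#' @param window Integer band half-width.
#' @param pruning Set `FALSE` to force a full DTW scan (used for the
#'   with/without-pruning comparisons; results are identical by construction).
#' @return A list of class `best_match` with `index` (1-based), `distance`
#'   (the true DTW distance), and `stats`, a named integer vector with
#'   `n_candidates`, `n_upper_bound_evals`, `n_lower_bound_evals`,
#'   `n_dtw_calls`, `n_pruned` (`n_pruned + n_dtw_calls == n_candidates`).
#' @export
find_best_match <- function(query, candidates, window, pruning = TRUE) {
  query <- as.numeric(query)
  if (anyNA(query)) stop_value("Query contains missing values.")
  cand <- candidate_matrix(candidates, length(query))
  if (anyNA(cand)) stop_value("Candidates contain missing values.")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_parameter("`window` must be an integer >= 1.")
  res <- best_match_impl(query, cand, window, pruning = pruning)
  structure(res, class = "best_match")
}
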