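#' Smooth class prototypes for synthetic benchmarks
#'
#' Generates `n_classes` distinct smooth shapes (sinusoids of varying
#' frequency and phase) of a common length, used as the ground-truth cluster
#' centres of the synthetic generator. Shapes are deterministic and pairwise
#' well separated under windowed DTW, so class structure survives the warping
#' and noise added by [synth_dataset()].
#'
#' @param n_classes Number of prototypes (>= 1).
#' @param length Series length `m`.
#' @return A list of `n_classes` numeric vectors.
#' @export
synth_prototypes <- function(n_classes, length = 60) {
  if (n_classes < 1) stop_parameter("`n_classes` must be >= 1.")
  m <- as.integer(length)
  if (m < 2L) stop_parameter("`length` must be >= 2.")
  t <- seq(0, 1, length.out = m)
  lapply(seq_len(n_classes), function(c) {
    freq <- 1 + (c - 1) %% 4
    phase <- 2 * pi * ((c - 1) %/% 4) / 4
    sin(2 * pi * freq * t + phase)
  })
}

#' Randomly warp a series along its time axis
#'
#' Applies a random monotone re-indexing with pointwise displacement at most
#' `warp_steps`: a smooth random displacement field is added to the index
#' vector, rounded, clipped to the valid range and sorted (sorting values each
#' within `warp_steps` of their position keeps every one within `warp_steps`
#' of its new position, so monotonicity and the displacement bound both hold).
#' The output has the same length; the source index of every output point is
#' attached as attribute `"warp_index"`.
#'
#' This is exactly the kind of local shift/stretch/squeeze that dynamic time
#' warping is designed to absorb, so warped copies stay DTW-close to their
#' prototype while drifting apart in Euclidean distance.
#'
#' @param s Numeric vector.
#' @param warp_steps Maximum index displacement (integer, `< length(s)`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A numeric vector of the same length with attribute `"warp_index"`.
#' @export
warp_series <- function(s, warp_steps, seed = NULL) {
  s <- as.numeric(s)
  m <- length(s)
  warp_steps <- as.integer(warp_steps)
  if (warp_steps < 0L || warp_steps >= m) {
    stop_parameter("`warp_steps` must satisfy 0 <= warp_steps < length(s).")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  if (warp_steps == 0L) {
    attr(s, "warp_index") <- seq_len(m)
    return(s)
  }
  drift <- cumsum(rnorm(m))
  drift <- drift - mean(drift)
  peak <- max(abs(drift), .Machine$double.eps)
  disp <- drift / peak * warp_steps
  idx <- sort(pmin(m, pmax(1L, as.integer(round(seq_len(m) + disp)))))
  out <- s[idx]
  attr(out, "warp_index") <- idx
  out
}

#' Generate a labelled synthetic time-series dataset
#'
#' Emits `per_class` copies of each prototype, each independently time-warped
#' (see [warp_series()]) and perturbed with Gaussian observation noise, then
#' shuffles the rows. The defaults (3 classes of 20 series, length 60, warp 3
#' — i.e. 5% of the length, matching the default DTW window — and noise
#' standard deviation 0.1 against unit-amplitude prototypes) give a dataset
#' whose class structure is recoverable by DTW clustering but not trivially
#' lock-step separable.
#'
#' @param n_classes Number of classes.
#' @param per_class Series per class.
#' @param length Series length `m`.
#' @param warp_steps Maximum warp displacement (`< length`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A dataset tibble with ground-truth integer labels `1..n_classes`.
#' @examples
#' d <- synth_dataset(seed = 7)
#' dplyr::count(d, label)
#' @export
synth_dataset <- function(n_classes = 3, per_class = 20, length = 60,
                          warp_steps = 3, noise_sd = 0.1, seed = 1L) {
  if (per_class < 1) stop_parameter("`per_class` must be >= 1.")
  if (noise_sd < 0) stop_parameter("`noise_sd` must be >= 0.")
  m <- as.integer(length)
  protos <- synth_prototypes(n_classes, m)
  withr::local_seed(as.integer(seed))
  values <- list()
  labels <- integer(0)
  for (c in seq_len(n_classes)) {
    for (r in seq_len(per_class)) {
      v <- warp_series(protos[[c]], warp_steps) + rnorm(m, sd = noise_sd)
      attr(v, "warp_index") <- NULL
      values <- c(values, list(v))
      labels <- c(labels, c)
    }
  }
  ord <- sample.int(length(values))
  ts_dataset(values[ord], labels = labels[ord])
}
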