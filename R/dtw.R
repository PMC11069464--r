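#' Euclidean distance between two equal-length series
#'
#' The pointwise (lock-step) distance. Because dynamic time warping minimises
#' the accumulated pointwise cost over all admissible alignments, and the
#' identity alignment is always admissible, this is a true upper bound on the
#' DTW distance under the squared-cost convention used throughout the package.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @examples
#' euclidean_distance(c(1, 2, 3), c(1, 1, 2)) # sqrt(2)
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop_length("Series must have equal lengths.")
  sqrt(sum((a - b)^2))
}

#' Warping window size from a length fraction
#'
#' Converts a relative window (default 5% of the series length, the setting
#' used for archive-wide clustering) into an absolute Sakoe-Chiba band
#' half-width: `W = max(1, floor(fraction * m))`.
#'
#' @param m Series length (>= 1).
#' @param fraction Window fraction in `(0, 1]`.
#' @return Integer window `W` with `1 <= W <= m`.
#' @examples
#' dtw_window(100, 0.05) # 5
#' dtw_window(10, 0.10)  # 1
#' @export
dtw_window <- function(m, fraction) {
  if (m < 1) stop_parameter("`m` must be >= 1.")
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop_parameter("`fraction` must lie in (0, 1].")
  }
  max(1L, as.integer(floor(fraction * m)))
}

#' Lower/upper envelope of a query series
#'
#' Running min/max band over the window `[i - W, i + W]` (clipped at the series
#' edges): `U_i = max(q_a, ..., q_b)`, `L_i = min(q_a, ..., q_b)` with
#' `a = i - W`, `b = i + W`. Candidates are compared against this band by
#' [lb_keogh()].
#'
#' @param q Numeric vector.
#' @param window Integer band half-width `W >= 1`.
#' @return An object of class `dtw_envelope`: list with `upper`, `lower`,
#'   `window`.
#' @examples
#' dtw_envelope(c(0, 2, 1, 3), window = 1)
#' @export
dtw_envelope <- function(q, window) {
  q <- as.numeric(q)
  if (length(q) < 1L) stop_empty("Series must have length >= 1.")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_parameter("`window` must be an integer >= 1.")
  env <- .envelope_cpp(q, window)
  structure(list(upper = env$upper, lower = env$lower, window = window),
            class = "dtw_envelope")
}

#' LB_Keogh lower bound on the windowed DTW distance
#'
#' Square root of the summed squared excursions of a candidate series outside
#' the query's envelope band: points above the upper boundary are penalised by
#' their squared distance to it, points below the lower boundary likewise, and
#' points inside the band contribute nothing. The result never exceeds the DTW
#' distance computed with the same window, which is what makes exact pruning
#' possible.
#'
#' @param t Candidate series, same length as the envelope.
#' @param envelope A [dtw_envelope()] of the query.
#' @return A non-negative scalar `<= dtw_distance(q, t, window)`.
#' @export
lb_keogh <- function(t, envelope) {
  t <- as.numeric(t)
  if (!inherits(envelope, "dtw_envelope")) {
    stop_parameter("`envelope` must be created by dtw_envelope().")
  }
  if (length(t) != length(envelope$upper)) {
    stop_length("Candidate and envelope must have equal lengths.")
  }
  .lb_keogh_cpp(t, envelope$upper, envelope$lower)
}

#' Windowed dynamic time warping distance
#'
#' Minimum accumulated squared pointwise cost over all warping paths that (i)
#' start at the first pair and end at the last, (ii) advance monotonically
#' without crossing, and (iii) stay within the Sakoe-Chiba band
#' `|i - j| <= window`; the square root of the accumulated cost is returned so
#' the value is commensurate with [euclidean_distance()], which bounds it from
#' above.
#'
#' @param q,c Numeric vectors of equal length.
#' @param window Integer band half-width `W >= 1`; `W = m` gives unconstrained
#'   DTW.
#' @return A non-negative scalar; `0` iff a perfect alignment exists.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 1, 2), window = 3) # 1, below sqrt(2)
#' @export
dtw_distance <- function(q, c, window) {
  q <- as.numeric(q)
  c <- as.numeric(c)
  if (length(q) != length(c)) stop_length("Series must have equal lengths.")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_parameter("`window` must be an integer >= 1.")
  if (anyNA(q) || anyNA(c)) stop_value("Series contain missing values.")
  .dtw_cpp(q, c, window)
}
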