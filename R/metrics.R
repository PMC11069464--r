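#' Contingency table between two labelings
#'
#' Cell (i, j) counts the observations carrying truth label i and predicted
#' label j; all six agreement indices are functions of this table alone, which
#' is what makes them invariant to label renaming.
#'
#' @param truth,pred Vectors of equal length (any atomic label type).
#' @return An integer matrix with truth labels as rows, predicted labels as
#'   columns, and dimnames giving the label values.
#' @export
contingency_table <- function(truth, pred) {
  if (length(truth) != length(pred)) stop_length("Labelings must have equal lengths.")
  if (length(truth) == 0L) stop_empty("Labelings are empty.")
  tab <- table(truth = truth, pred = pred)
  matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
         dimnames = dimnames(tab))
}

# Entropy (nats) of a count vector.
count_entropy <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  p <- counts / n
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model,
# the chance correction used by the adjusted mutual information.
expected_mi <- function(a, b, n) {
  lg <- lgamma
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        term <- (nij / n) * log((n * nij) / (ai * bj))
        lw <- lg(ai + 1) + lg(bj + 1) + lg(n - ai + 1) + lg(n - bj + 1) -
          lg(n + 1) - lg(nij + 1) - lg(ai - nij + 1) - lg(bj - nij + 1) -
          lg(n - ai - bj + nij + 1)
        emi <- emi + term * exp(lw)
      }
    }
  }
  emi
}

#' External clustering agreement indices
#'
#' Computes the six standard indices comparing a predicted labelling to a
#' reference: the Rand index (pair-agreement fraction), the adjusted Rand
#' index (Hubert-Arabie chance-corrected form), adjusted mutual information
#' (chance-corrected with the `max(H(U), H(V))` normaliser), homogeneity and
#' completeness (conditional-entropy forms; defined as 1 when the
#' corresponding entropy is zero), and the Fowlkes-Mallows score (geometric
#' mean of pairwise precision and recall). All are invariant to label
#' renaming; RI, ARI and FMS are symmetric in their arguments, and
#' homogeneity/completeness swap under argument exchange.
#'
#' @param truth Reference labels.
#' @param pred Predicted labels, same length (>= 2 observations).
#' @return A one-row tibble with columns `ari`, `ami`, `ri`, `homogeneity`,
#'   `completeness`, `fms`.
#' @examples
#' cluster_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1)) # ri = 1/3, ari = -0.5
#' @export
cluster_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) stop_length("Labelings must have equal lengths.")
  n <- length(truth)
  if (n < 2L) stop_degenerate("At least two observations are required.")
  tab <- contingency_table(truth, pred)
  a <- rowSums(tab)
  b <- colSums(tab)

  # pair counts
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(a))
  sum_b <- sum(choose2(b))
  total_pairs <- choose2(n)

  ri <- (total_pairs + 2 * sum_ij - sum_a - sum_b) / total_pairs
  exp_index <- sum_a * sum_b / total_pairs
  max_index <- (sum_a + sum_b) / 2
  ari <- if (abs(max_index - exp_index) < .Machine$double.eps) 1 else {
    (sum_ij - exp_index) / (max_index - exp_index)
  }
  fms <- if (sum_a == 0 || sum_b == 0) 0 else sum_ij / sqrt(sum_a * sum_b)

  # entropies and mutual information (nats)
  hu <- count_entropy(a)
  hv <- count_entropy(b)
  p <- tab / n
  nz <- tab > 0
  mi <- sum(p[nz] * log(p[nz] / outer(a / n, b / n)[nz]))
  h_c_given_k <- hu - mi
  h_k_given_c <- hv - mi
  homogeneity <- if (hu == 0) 1 else 1 - h_c_given_k / hu
  completeness <- if (hv == 0) 1 else 1 - h_k_given_c / hv

  ami <- if (hu == 0 && hv == 0) 1 else {
    emi <- expected_mi(a, b, n)
    normalizer <- max(hu, hv)
    denom <- normalizer - emi
    denom <- if (denom < 0) min(denom, -.Machine$double.eps) else max(denom, .Machine$double.eps)
    (mi - emi) / denom
  }

  tibble(ari = ari, ami = ami, ri = ri,
         homogeneity = homogeneity, completeness = completeness, fms = fms)
}

#' Summarise agreement indices over several runs or datasets
#'
#' Collapses a table of per-run indices (rows = runs, columns as produced by
#' [cluster_metrics()], plus any grouping columns) into means and standard
#' deviations per index, the layout used for multi-dataset benchmarking
#' summaries.
#'
#' @param results A data frame whose rows are individual [cluster_metrics()]
#'   results, optionally with extra id columns.
#' @param group Optional column name to group by (e.g. algorithm).
#' @return A tibble with one row per group and `<index>_mean` / `<index>_sd`
#'   columns.
#' @export
summarise_metrics <- function(results, group = NULL) {
  idx <- c("ari", "ami", "ri", "homogeneity", "completeness", "fms")
  idx <- intersect(idx, names(results))
  grouped <- if (!is.null(group)) dplyr::group_by(results, !!rlang::sym(group)) else results
  dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(idx),
                  list(mean = ~mean(.x), sd = ~stats::sd(.x)),
                  .names = "{.col}_{.fn}"),
    .groups = "drop"
  )
}
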