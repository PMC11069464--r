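# Independent oracles used to validate the fast implementations. These stay
# deliberately naive: full-matrix dynamic programming, exhaustive path
# enumeration, brute-force argmin, least-squares design matrices.

# Full (m+1)x(m+1) dynamic-programming DTW with a |i-j| <= w band,
# squared local cost, sqrt at the end.
dtw_oracle_dp <- function(q, c, w) {
  m <- length(q)
  D <- matrix(Inf, m + 1, m + 1)
  D[1, 1] <- 0
  for (i in 1:m) {
    for (j in max(1, i - w):min(m, i + w)) {
      D[i + 1, j + 1] <- (q[i] - c[j])^2 + min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  sqrt(D[m + 1, m + 1])
}

# Exhaustive enumeration of every legal warping path (monotone, boundary
# anchored, steps (1,0)/(0,1)/(1,1), band w). Only feasible for tiny m.
dtw_oracle_enum <- function(q, c, w) {
  m <- length(q)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + (q[i] - c[j])^2
    if (i == m && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    for (st in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      ni <- i + st[1]
      nj <- j + st[2]
      if (ni <= m && nj <= m && abs(ni - nj) <= w) rec(ni, nj, acc)
    }
  }
  rec(1L, 1L, 0)
  sqrt(best)
}

# Brute-force nearest candidate by the DP oracle; ties to the lowest index.
best_match_oracle <- function(query, cand_list, w) {
  d <- vapply(cand_list, function(c) dtw_oracle_dp(query, c, w), numeric(1))
  list(index = which.min(d), distance = min(d))
}

# Least-squares Savitzky-Golay projection matrix for a centred window: row
# (h+1) gives the central convolution weights.
sg_oracle_weights <- function(p, n) {
  h <- (n - 1) / 2
  X <- outer(-h:h, 0:p, `^`)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  H[h + 1, ]
}

# Brute-force pair-counting over all observation pairs (independent of the
# contingency-table shortcuts used in the package).
pair_counts_oracle <- function(truth, pred) {
  n <- length(truth)
  ss <- sd_ <- ds <- dd <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) ss <- ss + 1
      else if (st && !sp) sd_ <- sd_ + 1
      else if (!st && sp) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  c(ss = ss, sd = sd_, ds = ds, dd = dd)
}
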