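test_that("initialisation is seeded, reproducible, and samples dataset members", {
  d <- synth_dataset(n_classes = 3, per_class = 5, length = 30, seed = 4)
  g1 <- init_som(d, rows = 2, cols = 3, seed = 9)
  g2 <- init_som(d, rows = 2, cols = 3, seed = 9)
  expect_identical(g1$weights, g2$weights)
  X <- vapply(d$value, identity, numeric(30))
  member <- apply(g1$weights, 2, function(w) {
    any(apply(X, 2, function(x) isTRUE(all.equal(x, w))))
  })
  expect_true(all(member))

  # classification mode lays the mesh out as a single row of k nodes
  g3 <- init_som(d, k = 3)
  expect_identical(c(g3$rows, g3$cols), c(1L, 3L))
  expect_identical(ncol(g3$weights), 3L)
})

test_that("decay schedule is linear with the stated endpoints and monotone", {
  s0 <- decay_schedule(0, 100, alpha = 0.9, radius = 4)
  expect_equal(s0$learning_rate, 0.9)
  expect_equal(s0$radius, 4)
  s_last <- decay_schedule(99, 100, alpha = 0.9, radius = 4)
  expect_equal(s_last$learning_rate, 0.9 / 100)
  expect_equal(s_last$radius, 1)  # max(1, r0/E)
  lrs <- vapply(0:99, function(t) decay_schedule(t, 100, 0.9, 4)$learning_rate,
                numeric(1))
  rads <- vapply(0:99, function(t) decay_schedule(t, 100, 0.9, 4)$radius,
                 numeric(1))
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(diff(rads) <= 0))
  expect_error(decay_schedule(100, 100), class = "warpclust_error_parameter")
  expect_error(decay_schedule(-1, 100), class = "warpclust_error_parameter")
})

test_that("weight updates follow the Gaussian-kernel rule", {
  d <- ts_dataset(rbind(c(0, 0, 0), c(4, 4, 4)))
  som <- init_som(d, rows = 1, cols = 2, toroidal = FALSE, seed = 1)
  w_before <- som$weights

  # lr = 0 is a no-op
  expect_identical(update_weights(som, 1, c(9, 9, 9), 0, 1)$weights, w_before)

  # lr = 1, radius -> 0: the BMU becomes the query, everything else untouched
  som2 <- update_weights(som, 1, c(9, 9, 9), 1, 1e-13)
  expect_equal(som2$weights[, 1], c(9, 9, 9))
  expect_identical(som2$weights[, 2], w_before[, 2])

  # lr = 0.5, radius = 1: neighbour at grid distance 1 moves by
  # 0.5 * exp(-1/2) * (x - w) per point
  x <- c(10, 0, -2)
  som3 <- update_weights(som, 1, x, 0.5, 1)
  expect_equal(som3$weights[, 1], w_before[, 1] + 0.5 * (x - w_before[, 1]))
  expect_equal(som3$weights[, 2],
               w_before[, 2] + 0.5 * exp(-0.5) * (x - w_before[, 2]))
  expect_error(update_weights(som, 1, x, 1.5, 1), class = "warpclust_error_parameter")
})

test_that("toroidal grid distance wraps around the mesh", {
  d <- ts_dataset(rbind(c(0, 0), c(1, 1), c(2, 2)))
  som_t <- init_som(d, rows = 1, cols = 3, toroidal = TRUE, seed = 2)
  w0 <- som_t$weights
  x <- c(5, 5)
  upd <- update_weights(som_t, 1, x, 0.5, 1)
  # node 3 wraps to distance 1 from node 1, same pull as node 2
  move2 <- (upd$weights[, 2] - w0[, 2]) / (x - w0[, 2])
  move3 <- (upd$weights[, 3] - w0[, 3]) / (x - w0[, 3])
  expect_equal(move3, move2)
})

test_that("training converges on degenerate fixtures", {
  # one series, one node: the node weight is (and stays) that series
  one <- ts_dataset(matrix(sin(1:20 / 3), nrow = 1))
  fit1 <- train_som(one, rows = 1, cols = 1, epochs = 100, seed = 1)
  expect_equal(fit1$weights[, 1], one$value[[1]], tolerance = 1e-6)

  # two well-separated constant groups, 1 x 2 mesh
  flat <- ts_dataset(
    rbind(matrix(0, 10, 20), matrix(10, 10, 20)),
    labels = rep(1:2, each = 10)
  )
  # node weights settle on opposite sides of the two levels (the floored
  # neighbourhood radius keeps a residual pull between the two nodes, so the
  # fixed points are contractions of the class means, not the means exactly)
  fit2 <- train_som(flat, rows = 1, cols = 2, epochs = 50, seed = 3)
  levels <- sort(colMeans(fit2$weights))
  expect_lt(levels[1], 4)
  expect_gt(levels[2], 6)
  expect_equal(cluster_metrics(flat$label, predict(fit2, flat))$ari, 1)
})

test_that("pruning does not alter training: identical weights, BMUs and labels", {
  d <- synth_dataset(n_classes = 3, per_class = 8, length = 40, seed = 6)
  on <- train_som(d, k = 3, epochs = 20, seed = 6, pruning = TRUE)
  off <- train_som(d, k = 3, epochs = 20, seed = 6, pruning = FALSE)
  expect_identical(on$weights, off$weights)
  expect_identical(on$bmu_log, off$bmu_log)
  expect_identical(predict(on, d), predict(off, d, pruning = FALSE))
  # but pruning did strictly less DTW work
  expect_lt(sum(on$epoch_log$n_dtw_calls), sum(off$epoch_log$n_dtw_calls))
})

test_that("epoch log conserves counters and records the schedule", {
  d <- synth_dataset(n_classes = 2, per_class = 6, length = 30, seed = 2)
  fit <- train_som(d, rows = 2, cols = 2, epochs = 10, seed = 2)
  el <- fit$epoch_log
  expect_identical(nrow(el), 10L)
  expect_equal(el$n_pruned + el$n_dtw_calls, el$n_candidates)
  expect_equal(el$n_candidates, rep(12 * 4, 10))
  expect_true(all(diff(el$learning_rate) < 0))
  expect_equal(el$learning_rate[1], 0.9)
})

test_that("weights remain convex combinations of data and initial weights", {
  d <- synth_dataset(n_classes = 3, per_class = 6, length = 30, seed = 9)
  fit <- train_som(d, rows = 2, cols = 2, epochs = 15, seed = 9)
  X <- vapply(d$value, identity, numeric(30))
  lo <- pmin(apply(X, 1, min), apply(fit$init_weights, 1, min))
  hi <- pmax(apply(X, 1, max), apply(fit$init_weights, 1, max))
  expect_true(all(fit$weights >= lo - 1e-12))
  expect_true(all(fit$weights <= hi + 1e-12))
  expect_true(all(is.finite(fit$weights)))
})

test_that("assignment labels observations by BMU node index", {
  d <- synth_dataset(n_classes = 3, per_class = 6, length = 30, seed = 5)
  fit <- train_som(d, k = 3, epochs = 15, seed = 5)
  # a dataset equal to the node weights maps to nodes 1..k
  nodes <- ts_dataset(t(fit$weights))
  expect_identical(predict(fit, nodes), 1:3)
  # assignment is invariant to the pruning flag
  expect_identical(predict(fit, d, pruning = TRUE),
                   predict(fit, d, pruning = FALSE))
  # recovers generator classes on well-separated data
  expect_gte(cluster_metrics(d$label, predict(fit, d))$ari, 0.9)
})

test_that("U-matrix averages DTW distances to mesh neighbours", {
  d <- ts_dataset(rbind(c(0, 0, 0), c(1, 1, 1)))
  som <- init_som(d, rows = 1, cols = 2, toroidal = FALSE, seed = 1)

  # identical weights give an all-zero U-matrix
  som_same <- som
  som_same$weights[, 2] <- som_same$weights[, 1]
  expect_equal(som_umatrix(som_same)$value, c(0, 0))

  # a 1 x 2 mesh: both entries equal the single pairwise DTW distance
  um <- som_umatrix(som)
  d01 <- dtw_distance(som$weights[, 1], som$weights[, 2], som$window)
  expect_equal(um$value, c(d01, d01))

  # 2 x 2 mesh: hand-averaged neighbour distances
  set.seed(33)
  d4 <- ts_dataset(matrix(rnorm(4 * 12), nrow = 4))
  som4 <- init_som(d4, rows = 2, cols = 2, toroidal = FALSE, seed = 7)
  W <- som4$weights
  w <- som4$window
  dd <- function(a, b) dtw_distance(W[, a], W[, b], w)
  um4 <- som_umatrix(som4)
  # row-major flat layout: 1=(1,1), 2=(1,2), 3=(2,1), 4=(2,2)
  expect_equal(um4$value[1], mean(c(dd(1, 2), dd(1, 3))))
  expect_equal(um4$value[4], mean(c(dd(4, 2), dd(4, 3))))
})

test_that("a trained map survives a text export/import round trip", {
  d <- synth_dataset(n_classes = 2, per_class = 5, length = 24, seed = 8)
  fit <- train_som(d, k = 2, epochs = 8, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_som(fit, f)
  back <- read_som(f)
  expect_equal(back$weights, fit$weights)
  expect_identical(back$rows, fit$rows)
  expect_identical(predict(back, d), predict(fit, d))
  expect_equal(som_umatrix(back)$value, som_umatrix(fit)$value)

  um_file <- withr::local_tempfile(fileext = ".tsv")
  write_umatrix(fit, um_file)
  grid <- as.matrix(utils::read.table(um_file, sep = "\t"))
  expect_equal(dim(grid), c(1, 2))
})
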