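test_that("the archive dialect reader parses labels and values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t0.0\t1.0", "2\t1.0\t0.0"), f)
  d <- read_ucr(f)
  expect_identical(nrow(d), 2L)
  expect_identical(lengths(d$value), c(2L, 2L))
  expect_identical(d$label, c(1L, 2L))
  expect_equal(d$value[[1]], c(0, 1))
})

test_that("ragged, empty and malformed files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t0.0\t1.0", "2\t1.0"), f)
  expect_error(read_ucr(f), class = "warpclust_error_format")
  writeLines(character(0), f)
  expect_error(read_ucr(f), class = "warpclust_error_empty")
  writeLines(c("x\t0.0\t1.0"), f)
  expect_error(read_ucr(f), class = "warpclust_error_format")
})

test_that("write/read round-trips are bit-identical, including comma dialect", {
  d <- synth_dataset(n_classes = 2, per_class = 5, length = 30, seed = 14)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ucr(d, f)
  back <- read_ucr(f)
  expect_identical(back$label, d$label)
  expect_identical(back$value, d$value)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ucr(d, f2, sep = ",")
  back2 <- read_ucr(f2, sep = ",")
  expect_identical(back2$value, d$value)
})

test_that("dataset constructor validates lengths, finiteness and problem size", {
  expect_error(ts_dataset(list(c(1, 2), c(1, 2, 3))), class = "warpclust_error_length")
  expect_error(ts_dataset(list(c(1, Inf))), class = "warpclust_error_value")
  expect_error(ts_dataset(list()), class = "warpclust_error_empty")
  d <- ts_dataset(matrix(rnorm(12), nrow = 3))
  expect_identical(problem_size(d), 12L)
})

test_that("run reports evaluate stored labels and account for every comparison", {
  d <- synth_dataset(n_classes = 3, per_class = 10, length = 40, seed = 17)
  rep_som <- run_cluster(d, "som", k = 3, epochs = 30, seed = 17)
  expect_gte(rep_som$metrics$ari, 0.9)
  expect_equal(rep_som$total_dtw_calls, sum(rep_som$stats$n_dtw_calls))
  expect_equal(rep_som$pruning_fraction,
               1 - rep_som$total_dtw_calls / rep_som$total_comparisons)
  expect_identical(rep_som$problem_size, 40L * 30L)

  rep_km <- run_cluster(d, "kmeans", k = 1, seed = 17)
  expect_equal(rep_km$metrics$completeness, 1)

  # labels never leak into training: an unlabelled copy trains identically
  d_unlab <- d
  d_unlab$label <- NA_integer_
  rep_unlab <- run_cluster(d_unlab, "som", k = 3, epochs = 30, seed = 17)
  expect_identical(rep_unlab$labels, rep_som$labels)
  expect_null(rep_unlab$metrics)
})

test_that("the with/without-pruning comparison reports identical labels", {
  d <- synth_dataset(n_classes = 2, per_class = 8, length = 30, seed = 19)
  rep <- run_cluster(d, "kmeans", k = 2, seed = 19, compare_pruning = TRUE)
  expect_true(rep$pruning_comparison$labels_identical)
  expect_lte(rep$pruning_comparison$dtw_calls_with,
             rep$pruning_comparison$dtw_calls_without)

  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_true(doc$pruning_comparison$labels_identical)
  expect_identical(as.integer(doc$labels), as.integer(rep$labels))
})

test_that("the CLI clusters, evaluates and re-loads byte-reproducibly", {
  dir <- withr::local_tempdir()
  data_f <- file.path(dir, "d.tsv")
  labels_f <- file.path(dir, "labels.csv")
  labels_f2 <- file.path(dir, "labels2.csv")
  report_f <- file.path(dir, "report.json")
  model_f <- file.path(dir, "model.json")

  expect_identical(run_cli(c("synth", "--classes", "3", "--per-class", "10",
                             "--length", "40", "--seed", "7", "-o", data_f)), 0L)
  expect_true(file.exists(data_f))

  st <- run_cli(c("cluster", "som", data_f, "--k", "3", "--epochs", "10",
                  "--seed", "7", "--labels-out", labels_f,
                  "--report-out", report_f, "--model-out", model_f))
  expect_identical(st, 0L)
  expect_true(all(file.exists(labels_f, report_f, model_f)))

  # same seed without pruning: byte-identical label output
  st2 <- run_cli(c("cluster", "som", data_f, "--k", "3", "--epochs", "10",
                   "--seed", "7", "--no-pruning", "--labels-out", labels_f2,
                   "--report-out", file.path(dir, "r2.json")))
  expect_identical(st2, 0L)
  expect_identical(readLines(labels_f), readLines(labels_f2))

  out <- capture.output(st3 <- run_cli(c("evaluate", data_f, labels_f)))
  expect_identical(st3, 0L)
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_true(all(c("ari", "ami", "ri", "homogeneity", "completeness", "fms")
                  %in% names(parsed)))

  um_f <- file.path(dir, "um.tsv")
  expect_identical(run_cli(c("umatrix", model_f, "-o", um_f)), 0L)
  expect_identical(dim(as.matrix(utils::read.table(um_f, sep = "\t"))), c(1L, 3L))

  expect_identical(suppressMessages(run_cli(c("cluster", "som", data_f,
                                              "--bogus-flag"))), 2L)
  expect_identical(suppressMessages(run_cli(c("nonsense"))), 2L)
})

test_that("the CLI narrative stage writes archive-dialect series", {
  dir <- withr::local_tempdir()
  tok_f <- file.path(dir, "tokens.tsv")
  out_f <- file.path(dir, "series.tsv")
  tokens <- make_token_corpus(n_future = 2, n_past = 2, words = 2500, seed = 3)
  utils::write.table(tokens, tok_f, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  expect_identical(suppressMessages(
    run_cli(c("narrative", tok_f, "--min-words", "2000", "-o", out_f))), 0L)
  series <- read_ucr(out_f)
  expect_identical(nrow(series), 4L)
  expect_true(all(lengths(series$value) == 10))
})
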