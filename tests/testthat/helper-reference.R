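# Reference implementation bridge: scikit-learn (through the system python)
# computes the six agreement indices for batches of label pairs. Used as an
# implementation-independent cross-check of cluster_metrics().

sklearn_script <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- tempfile(fileext = ".py")
      writeLines(c(
        "import json, sys",
        "from sklearn import metrics as M",
        "d = json.load(open(sys.argv[1]))",
        "out = []",
        "for t, p in zip(d['t'], d['p']):",
        "    out.append(dict(",
        "        ari=M.adjusted_rand_score(t, p),",
        "        ami=M.adjusted_mutual_info_score(t, p, average_method='max'),",
        "        ri=M.rand_score(t, p),",
        "        homogeneity=M.homogeneity_score(t, p),",
        "        completeness=M.completeness_score(t, p),",
        "        fms=M.fowlkes_mallows_score(t, p)))",
        "json.dump(out, open(sys.argv[2], 'w'))"
      ), path)
    }
    path
  }
})

# pairs_t / pairs_p: lists of integer label vectors. Returns a data frame of
# the six indices, one row per pair.
sklearn_reference <- function(pairs_t, pairs_p) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(t = pairs_t, p = pairs_p), fin)
  status <- system2("python", c(sklearn_script(), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::fromJSON(fout)
}

# Seeded synthetic conversation token streams for the narrative stage: two
# groups, one whose talk leans toward the future and one toward the past,
# with an arc (future proportion drifting over narrative time).
make_token_corpus <- function(n_future = 20, n_past = 20, words = 2500,
                              verb_rate = 0.08, seed = 1) {
  withr::local_seed(seed)
  rows <- list()
  mk <- function(cid, base) {
    pos <- which(runif(words) < verb_rate)
    frac <- pos / words
    p_future <- pmin(0.95, pmax(0.05, base + 0.15 * sin(2 * pi * frac)))
    tag <- ifelse(runif(length(pos)) < p_future, "future", "past")
    # sprinkle untagged/present words; they must never affect the series
    extra <- which(runif(words) < 0.05)
    tibble::tibble(
      conversation = cid,
      position = c(pos, extra, words),
      tag = c(tag, rep("none", length(extra)), "present")
    )
  }
  for (i in seq_len(n_future)) rows[[length(rows) + 1]] <- mk(sprintf("fut%02d", i), 0.75)
  for (i in seq_len(n_past)) rows[[length(rows) + 1]] <- mk(sprintf("pst%02d", i), 0.25)
  dplyr::arrange(dplyr::bind_rows(rows), conversation, position)
}
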