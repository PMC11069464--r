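#' Read temporal-reference tagged tokens
#'
#' Tab-separated, no header, three fields per line: conversation id, word
#' position within the conversation (1-based), and a temporal-reference tag,
#' one of `past`, `present`, `future`, `none`. Words that are not verbs (or
#' carry no temporal reference) are tagged `none`; only `past` and `future`
#' enter the narrative-arc ratio.
#'
#' @param path Path to the token file.
#' @return A tibble with columns `conversation`, `position`, `tag`.
#' @export
read_tokens <- function(path) {
  if (!file.exists(path)) stop_format(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(conversation = character(), position = integer(), tag = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L)) {
    stop_format("Token files need exactly three tab-separated fields per line.")
  }
  tags <- vapply(fields, `[[`, character(1), 3L)
  bad <- setdiff(unique(tags), c("past", "present", "future", "none"))
  if (length(bad) > 0L) {
    stop_format(paste0("Unknown temporal-reference tag(s): ",
                       paste(bad, collapse = ", ")))
  }
  tibble(
    conversation = vapply(fields, `[[`, character(1), 1L),
    position = as.integer(vapply(fields, `[[`, character(1), 2L)),
    tag = tags
  )
}

#' Decile narrative-arc series of a conversation
#'
#' Splits a conversation into ten equal "narrative time" bins by word count
#' (decile `d`, 0-based, covers 0-based word offsets
#' `[floor(d * total / 10), floor((d + 1) * total / 10))`) and, within each
#' bin, computes the proportion of future-tense verbs among all past- and
#' future-tense verbs. Values above 0.5 mean more future talk than past talk.
#' `present`/`none` tokens never affect the result; a bin containing no past
#' or future verbs is set to the neutral value 0.5, the decision threshold
#' itself.
#'
#' @param positions Integer word positions (1-based) of the tagged tokens.
#' @param tags Character tags (`past`, `present`, `future`, `none`), parallel
#'   to `positions`.
#' @param total_words Total word count of the conversation (>= 10).
#' @return A numeric vector of length 10 with values in `[0, 1]`.
#' @examples
#' decile_series(c(1, 5, 12, 18), c("future", "past", "future", "future"), 20)
#' @export
decile_series <- function(positions, tags, total_words) {
  if (total_words < 10) stop_too_short("`total_words` must be at least 10.")
  if (length(positions) != length(tags)) {
    stop_length("`positions` and `tags` must be parallel vectors.")
  }
  keep <- tags %in% c("past", "future")
  positions <- as.integer(positions[keep])
  tags <- tags[keep]
  breaks <- floor(seq_len(10) * total_words / 10)  # right edges, 0-based exclusive
  dec <- findInterval(positions - 1L, c(0, breaks), rightmost.closed = FALSE)
  dec[dec > 10L] <- 10L  # guard positions at/after total_words
  vapply(seq_len(10), function(d) {
    fut <- sum(dec == d & tags == "future")
    pst <- sum(dec == d & tags == "past")
    if (fut + pst == 0L) 0.5 else fut / (fut + pst)
  }, numeric(1))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing: each point is replaced by the value at
#' its position of a polynomial of the given order fitted over the centred
#' moving window (the classical 2nd-order, 9-step filter by default). Points
#' too close to the ends, where no centred window fits, take the value of the
#' polynomial fitted on the nearest full window, evaluated at their position —
#' no padded data is invented. The filter is linear and reproduces any
#' polynomial up to the fitted order exactly, so constant and linear series
#' pass through unchanged.
#'
#' @param x Numeric vector.
#' @param order Polynomial order (default 2), `order < window`.
#' @param window Odd window length (default 9), `window <= length(x)`.
#' @return The smoothed numeric vector (not clamped; see [build_corpus()]).
#' @export
savgol_smooth <- function(x, order = 2, window = 9) {
  x <- as.numeric(x)
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L == 0L || window < 1L) stop_parameter("`window` must be odd and >= 1.")
  if (order < 0L || order >= window) stop_parameter("`order` must satisfy 0 <= order < window.")
  if (window > length(x)) stop_parameter("`window` cannot exceed the series length.")
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Build a corpus of smoothed narrative-arc series
#'
#' Filters out conversations shorter than `min_words` (short conversations
#' give sparse decile counts), then maps every survivor through
#' [decile_series()] and [savgol_smooth()] and clamps the smoothed values to
#' `[0, 1]` (the polynomial fit can overshoot the proportion scale). The
#' result feeds the clustering engines unchanged.
#'
#' @param tokens A tibble of tagged tokens (`conversation`, `position`, `tag`),
#'   as returned by [read_tokens()]. The word count of a conversation is taken
#'   as its maximum token position.
#' @param min_words Minimum conversation length in words (default 2000,
#'   roughly a 15-minute conversation at typical speaking rates).
#' @param order,window Savitzky-Golay parameters (defaults 2 and 9).
#' @return A dataset tibble (id = conversation, `label = NA`, `value` =
#'   length-10 smoothed series) plus a `word_count` column; zero rows when no
#'   conversation passes the filter.
#' @export
build_corpus <- function(tokens, min_words = 2000, order = 2, window = 9) {
  if (!all(c("conversation", "position", "tag") %in% names(tokens))) {
    stop_format("`tokens` needs columns conversation, position, tag.")
  }
  ids <- unique(tokens$conversation)
  rows <- list()
  counts <- integer(0)
  for (cid in ids) {
    tk <- tokens[tokens$conversation == cid, ]
    total <- max(tk$position)
    if (total < min_words) next
    raw <- decile_series(tk$position, tk$tag, total)
    sm <- pmin(1, pmax(0, savgol_smooth(raw, order = order, window = window)))
    rows <- c(rows, list(sm))
    counts <- c(counts, total)
    names(rows)[length(rows)] <- cid
  }
  if (length(rows) == 0L) {
    return(tibble(id = character(), label = integer(), value = list(),
                  word_count = integer()))
  }
  out <- ts_dataset(rows, ids = names(rows))
  out$word_count <- counts
  out
}
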