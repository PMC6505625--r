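# Data model: message corpora and happiness lexicons, plus the line-delimited
# interchange formats the pipeline reads and writes.

REQUIRED_MESSAGE_FIELDS <- c("user_id", "message_id", "time_utc", "lat", "lon", "text")

#' Construct a message corpus
#'
#' A corpus holds geolocated messages, one row per message, grouped by an
#' opaque user id and sorted by time within user. Timestamps are stored in
#' UTC together with an explicit local offset in minutes; local analyses
#' (e.g. diurnal cycles) use `time_utc + 60 * utc_offset_min`.
#'
#' @param messages A data frame with columns `user_id`, `message_id`,
#'   `time_utc` (POSIXct, UTC), `lat`, `lon` (WGS84 decimal degrees),
#'   `text`, and optionally `utc_offset_min` (integer minutes, `NA` when
#'   unknown) and `is_checkin` (logical, set by [detect_checkin()]).
#' @return An object of class `gh_corpus`: a tibble sorted by user then time,
#'   with the validated column set above.
#' @export
corpus <- function(messages) {
  m <- tibble::as_tibble(messages)
  missing_cols <- setdiff(REQUIRED_MESSAGE_FIELDS, names(m))
  abort_if(length(missing_cols) > 0,
           "corpus is missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  if (!"utc_offset_min" %in% names(m)) m$utc_offset_min <- NA_integer_
  if (!"is_checkin" %in% names(m)) m$is_checkin <- FALSE
  m$user_id <- as.character(m$user_id)
  m$message_id <- as.character(m$message_id)
  if (!inherits(m$time_utc, "POSIXct")) {
    m$time_utc <- as.POSIXct(m$time_utc, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                            "%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  }
  attr(m$time_utc, "tzone") <- "UTC"
  abort_if(anyNA(m$lat) || anyNA(m$lon), "corpus has missing coordinates")
  abort_if(any(m$lat < -90 | m$lat > 90), "latitude outside [-90, 90]")
  abort_if(any(m$lon < -180 | m$lon > 180), "longitude outside [-180, 180]")
  abort_if(anyDuplicated(m$message_id) > 0, "duplicate message_id in corpus")
  m <- m[order(m$user_id, m$time_utc, m$message_id), , drop = FALSE]
  class(m) <- c("gh_corpus", class(m))
  m
}

#' @export
print.gh_corpus <- function(x, ...) {
  cat(sprintf("<gh_corpus> %d messages from %d users\n",
              nrow(x), length(unique(x$user_id))))
  NextMethod()
}

#' Per-user message counts
#'
#' @param corpus A [corpus()] object.
#' @return A tibble with columns `user_id` and `n`.
#' @export
user_counts <- function(corpus) {
  t <- table(corpus$user_id)
  tibble::tibble(user_id = names(t), n = as.integer(t))
}

#' Split a corpus into per-user message tables
#'
#' @param corpus A [corpus()] object.
#' @return A named list of tibbles, one per user, in user-id order.
#' @export
split_users <- function(corpus) {
  split(tibble::as_tibble(corpus), corpus$user_id)
}

#' Read a message corpus from line-delimited JSON
#'
#' Each line is one JSON object with fields `user_id`, `message_id`,
#' `time_utc` (ISO-8601), `utc_offset_min` (optional), `lat`, `lon`, `text`.
#' Records missing a required field or with out-of-range coordinates are
#' skipped and counted, not fatal; an unreadable file is fatal.
#'
#' @param path File to read.
#' @param dialect Format tag; `"jsonl"` (default) or `"tsv"` (tab-separated
#'   with a header line and the same field names).
#' @param quiet Suppress the skipped-record message.
#' @return A `gh_corpus`; the number of skipped records is available as
#'   `attr(x, "n_skipped")`.
#' @export
read_messages <- function(path, dialect = c("jsonl", "tsv"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  abort_if(!file.exists(path), "cannot read messages: no such file '%s'", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "tsv" && length(lines) > 0) {
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
    parse_one <- function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != length(header)) return(NULL)
      stats::setNames(as.list(f), header)
    }
  } else {
    parse_one <- function(ln) {
      tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    }
  }
  if (length(lines) == 0) {
    return(empty_corpus())
  }
  recs <- lapply(lines, parse_one)
  ok <- vapply(recs, function(r) {
    is.list(r) &&
      all(REQUIRED_MESSAGE_FIELDS %in% names(r)) &&
      !is.na(suppressWarnings(as.numeric(r$lat))) &&
      !is.na(suppressWarnings(as.numeric(r$lon))) &&
      as.numeric(r$lat) >= -90 && as.numeric(r$lat) <= 90 &&
      as.numeric(r$lon) >= -180 && as.numeric(r$lon) <= 180
  }, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0 && !quiet) {
    message(sprintf("read_messages: skipped %d malformed or out-of-range record(s)",
                    n_skipped))
  }
  recs <- recs[ok]
  if (length(recs) == 0) {
    out <- empty_corpus()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  get_chr <- function(f) vapply(recs, function(r) as.character(r[[f]]), character(1))
  get_num <- function(f) vapply(recs, function(r) as.numeric(r[[f]]), numeric(1))
  off <- vapply(recs, function(r) {
    v <- r[["utc_offset_min"]]
    if (is.null(v) || is.na(suppressWarnings(as.numeric(v)))) NA_integer_
    else as.integer(as.numeric(v))
  }, integer(1))
  out <- corpus(tibble::tibble(
    user_id = get_chr("user_id"),
    message_id = get_chr("message_id"),
    time_utc = as.POSIXct(get_chr("time_utc"), tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                         "%Y-%m-%dT%H:%M:%S",
                                         "%Y-%m-%d %H:%M:%S")),
    utc_offset_min = off,
    lat = get_num("lat"),
    lon = get_num("lon"),
    text = get_chr("text")
  ))
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_corpus <- function() {
  out <- corpus(tibble::tibble(
    user_id = character(), message_id = character(),
    time_utc = as.POSIXct(character(), tz = "UTC"),
    utc_offset_min = integer(),
    lat = numeric(), lon = numeric(), text = character()
  ))
  attr(out, "n_skipped") <- 0L
  out
}

#' Write a message corpus as line-delimited JSON
#'
#' Inverse of [read_messages()]: `read_messages(write_messages(x, p))`
#' reproduces `x`.
#'
#' @param corpus A `gh_corpus`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_messages <- function(corpus, path) {
  fields <- c("user_id", "message_id", "time_utc", "utc_offset_min",
              "lat", "lon", "text")
  df <- as.data.frame(corpus)[, fields, drop = FALSE]
  df$time_utc <- format(df$time_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df) > 0) {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      if (is.na(rec$utc_offset_min)) rec$utc_offset_min <- NULL
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a happiness lexicon
#'
#' Reads a two-column tab-separated file `word<TAB>score` (no header) into a
#' lexicon of average word-happiness scores on the 1 (sad) to 9 (happy)
#' scale. The packaged example lexicon, a 15-word crowd-scored (labMT-style)
#' excerpt, is at `system.file("extdata", "table1.tsv", package = "geohedon")`.
#'
#' @param path Lexicon file.
#' @param neutral_delta Half-width of the neutral exclusion band around 5;
#'   words with scores strictly inside `(5 - neutral_delta, 5 + neutral_delta)`
#'   are ignored by the hedonometer. Default 1 (band (4, 6)).
#' @return A `gh_lexicon`: a tibble with columns `word` and `score`, carrying
#'   `neutral_delta` as an attribute.
#' @export
read_lexicon <- function(path, neutral_delta = 1) {
  abort_if(!file.exists(path), "cannot read lexicon: no such file '%s'", path)
  raw <- utils::read.delim(path, header = FALSE, quote = "",
                           col.names = c("word", "score"),
                           colClasses = c("character", "numeric"),
                           fileEncoding = "UTF-8")
  lexicon(raw$word, raw$score, neutral_delta = neutral_delta)
}

#' Construct a lexicon from words and scores
#'
#' @param words Character vector of unique lexicon tokens (may include
#'   emoticons such as `":("`).
#' @param scores Numeric scores in `[1, 9]`, one per word.
#' @inheritParams read_lexicon
#' @return A `gh_lexicon` tibble.
#' @export
lexicon <- function(words, scores, neutral_delta = 1) {
  abort_if(length(words) != length(scores), "words and scores differ in length")
  dup <- words[duplicated(words)]
  abort_if(length(dup) > 0,
           "duplicate lexicon word(s) with ambiguous scores: %s",
           paste(unique(dup), collapse = ", "))
  abort_if(any(!is.finite(scores)) || any(scores < 1 | scores > 9),
           "lexicon scores must lie in [1, 9]")
  abort_if(!is.numeric(neutral_delta) || neutral_delta < 0,
           "neutral_delta must be a non-negative number")
  out <- tibble::tibble(word = as.character(words), score = as.numeric(scores))
  attr(out, "neutral_delta") <- neutral_delta
  class(out) <- c("gh_lexicon", class(out))
  out
}

#' @export
print.gh_lexicon <- function(x, ...) {
  cat(sprintf("<gh_lexicon> %d words, neutral band (%.2f, %.2f)\n",
              nrow(x), 5 - attr(x, "neutral_delta"), 5 + attr(x, "neutral_delta")))
  NextMethod()
}

#' Path to the packaged example lexicon
#'
#' @return Path of the 15-word labMT-style example lexicon shipped with the
#'   package.
#' @export
example_lexicon_path <- function() {
  system.file("extdata", "table1.tsv", package = "geohedon", mustWork = TRUE)
}

#' Write and read result tables
#'
#' Plain comma-separated tables with a header line; values round-trip
#' through [read_table()].
#'
#' @param rows A data frame.
#' @param path Output file.
#' @return `path` invisibly (`write_table`); a tibble (`read_table`).
#' @export
write_table <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  abort_if(!file.exists(path), "no such table: '%s'", path)
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                    stringsAsFactors = FALSE))
}
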