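# Lexicon-based happiness measurement. A text's average happiness is the
# frequency-weighted mean of per-word scores over lexicon words outside a
# neutral band around 5; per-tweet sentiment is deliberately never assigned.

#' Tokenize a text
#'
#' Lowercases, extracts lexicon tokens containing punctuation (emoticons
#' such as `":("`) by longest match first so they survive punctuation
#' stripping, then splits the remainder on whitespace and strips leading
#' and trailing punctuation (internal apostrophes are kept, so
#' contractions like `"i'm"` remain single tokens).
#'
#' @param text Character vector of texts.
#' @param lexicon Optional `gh_lexicon`; only its tokens containing
#'   non-alphanumeric characters affect tokenization.
#' @return A list of character vectors, one per input text.
#' @export
tokenize <- function(text, lexicon = NULL) {
  text <- tolower(as.character(text))
  specials <- character(0)
  if (!is.null(lexicon)) {
    specials <- lexicon$word[grepl("[^a-z0-9']", lexicon$word)]
    specials <- specials[order(-nchar(specials))]
  }
  n <- length(text)
  special_counts <- vector("list", n)
  if (length(specials) > 0) {
    for (s in specials) {
      hits <- gregexpr(s, text, fixed = TRUE)
      cnt <- vapply(hits, function(h) if (h[1] == -1) 0L else length(h), integer(1))
      text <- gsub(s, " ", text, fixed = TRUE)
      for (i in which(cnt > 0)) {
        special_counts[[i]] <- c(special_counts[[i]], rep(s, cnt[i]))
      }
    }
  }
  parts <- strsplit(text, "[[:space:]]+")
  lapply(seq_len(n), function(i) {
    w <- parts[[i]]
    w <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", w)
    w <- w[nzchar(w)]
    c(w, special_counts[[i]])
  })
}

#' Count words in texts
#'
#' @param text Character vector of texts (pooled into one bag of words).
#' @param lexicon Optional lexicon forwarded to [tokenize()].
#' @return A named integer vector of word counts (a bag-of-words).
#' @export
word_counts <- function(text, lexicon = NULL) {
  toks <- unlist(tokenize(text, lexicon), use.names = FALSE)
  if (length(toks) == 0) return(stats::setNames(integer(0), character(0)))
  t <- table(toks)
  stats::setNames(as.integer(t), names(t))
}

# words of `counts` that are in the lexicon and outside the open neutral band
scorable_words <- function(counts, lexicon, delta) {
  w <- names(counts)
  idx <- match(w, lexicon$word)
  h <- lexicon$score[idx]
  keep <- !is.na(h) & !(h > 5 - delta & h < 5 + delta)
  keep
}

#' Average happiness of a bag of words
#'
#' The hedonometer score: `h_avg = sum(h(w) f(w)) / sum(f(w))` over words
#' with a lexicon score outside the open neutral band
#' `(5 - delta, 5 + delta)`. With the default `delta = 1`, words scored
#' strictly between 4 and 6 are ignored; scores of exactly 4 or 6 are kept.
#'
#' @param counts Named integer vector of word counts, as from
#'   [word_counts()].
#' @param lexicon A `gh_lexicon`.
#' @param delta Neutral band half-width; defaults to the lexicon's
#'   `neutral_delta` attribute (1 unless changed).
#' @return The score in `[1, 9]`, or `NA_real_` when no counted word is
#'   scorable (an explicit no-score result, never silently 0).
#' @export
score_counts <- function(counts, lexicon, delta = NULL) {
  delta <- delta %||% attr(lexicon, "neutral_delta") %||% 1
  if (length(counts) == 0) return(NA_real_)
  keep <- scorable_words(counts, lexicon, delta)
  if (!any(keep)) return(NA_real_)
  f <- as.numeric(counts[keep])
  h <- lexicon$score[match(names(counts)[keep], lexicon$word)]
  sum(h * f) / sum(f)
}

#' Average happiness of texts
#'
#' Convenience wrapper: tokenizes `text`, pools the words, and scores the
#' bag with [score_counts()].
#'
#' @param text Character vector of texts, pooled into one bag.
#' @inheritParams score_counts
#' @return The pooled score, or `NA_real_` if nothing is scorable.
#' @export
score_text <- function(text, lexicon, delta = NULL) {
  score_counts(word_counts(text, lexicon), lexicon, delta)
}

#' Equal-count bin assignment
#'
#' Sorts entities ascending by value (stable, so ties keep input order) and
#' splits them into `k` contiguous groups whose sizes differ by at most
#' one; when `n` is not a multiple of `k` the first `n %% k` groups take
#' the extra entity.
#'
#' @param values Numeric vector.
#' @param k Number of bins.
#' @return Integer bin index (1..k) per entity, in input order.
#' @export
equal_count_bins <- function(values, k) {
  n <- length(values)
  abort_if(k < 1, "k must be at least 1")
  abort_if(n < k, "cannot split %d values into %d equal-count bins", n, k)
  ord <- order(values)  # stable
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(k), times = sizes)
  bins
}

#' Happiness as a function of distance from expected location
#'
#' Groups sentiment-eligible messages into `k` equal-count bins by their
#' distance from the author's expected location, pools all words in each
#' bin into a single bag, and scores each bag once. Word pooling (rather
#' than averaging per-message scores) is the point: single tweets are too
#' short for a stable score.
#'
#' @param text Message texts.
#' @param distance_m Per-message distance from the author's expected
#'   location, meters (see [mobility_table()]).
#' @param lexicon A `gh_lexicon`.
#' @param k Number of equal-count bins (default 10).
#' @param delta Neutral band half-width override.
#' @return A tibble (`gh_binned_trend`) with `bin`, `d_lo`, `d_hi`,
#'   `d_median` (bin median distance, the representative distance for
#'   trend fits), `n_messages`, `n_words` (scorable word count) and
#'   `h_avg` (`NA` for bins with no scorable words).
#' @export
happiness_by_distance <- function(text, distance_m, lexicon, k = 10, delta = NULL) {
  abort_if(length(text) != length(distance_m),
           "text and distance_m lengths differ")
  bins <- equal_count_bins(distance_m, k)
  binned_trend(text, distance_m, bins, k, lexicon, delta)
}

#' Happiness as a function of gyradius
#'
#' Groups *users* into `k` equal-count bins by gyradius, pools all words
#' authored by each bin's users, and scores each pooled bag once.
#'
#' @param text Message texts.
#' @param user_id Author of each message.
#' @param gyradius_m Named per-user gyradii (names are user ids).
#' @inheritParams happiness_by_distance
#' @return As [happiness_by_distance()], with `d_*` columns referring to
#'   gyradius.
#' @export
happiness_by_gyradius <- function(text, user_id, gyradius_m, lexicon, k = 10,
                                  delta = NULL) {
  users <- names(gyradius_m)
  ubins <- equal_count_bins(as.numeric(gyradius_m), k)
  mbin <- ubins[match(user_id, users)]
  keep <- !is.na(mbin)
  binned_trend(text[keep], gyradius_m[match(user_id[keep], users)],
               mbin[keep], k, lexicon, delta)
}

binned_trend <- function(text, value, bins, k, lexicon, delta) {
  rows <- lapply(seq_len(k), function(b) {
    sel <- bins == b
    if (!any(sel)) {
      return(tibble::tibble(bin = b, d_lo = NA_real_, d_hi = NA_real_,
                            d_median = NA_real_, n_messages = 0L,
                            n_words = 0L, h_avg = NA_real_))
    }
    counts <- word_counts(text[sel], lexicon)
    keep <- scorable_words(counts, lexicon,
                           delta %||% attr(lexicon, "neutral_delta") %||% 1)
    tibble::tibble(bin = b,
                   d_lo = min(value[sel]), d_hi = max(value[sel]),
                   d_median = stats::median(value[sel]),
                   n_messages = sum(sel),
                   n_words = sum(counts[keep]),
                   h_avg = score_counts(counts, lexicon, delta))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gh_binned_trend", class(out))
  out
}

#' Fit a log-distance happiness trend
#'
#' Least squares of bin happiness on `log10(distance)`; used for the
#' logarithmic increase of happiness with distance (or gyradius) beyond
#' the commute-scale dip.
#'
#' @param distance_m Representative bin distances (e.g. `d_median`), > 0.
#' @param h_avg Bin happiness scores.
#' @param min_distance_m Bins at or below this distance are excluded
#'   (default 0: keep all), so the fit can start beyond the dip.
#' @return A list with `slope`, `intercept`, `n`.
#' @export
fit_log_linear <- function(distance_m, h_avg, min_distance_m = 0) {
  keep <- !is.na(h_avg) & distance_m > min_distance_m & distance_m > 0
  abort_if(sum(keep) < 2, "fit_log_linear needs at least 2 scored bins")
  fit <- stats::lm(h_avg[keep] ~ log10(distance_m[keep]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = sum(keep))
}
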