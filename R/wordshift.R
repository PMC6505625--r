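# Word shifts: exact decomposition of the happiness difference between a
# reference and a comparison text into ranked per-word contributions.

#' Word shift between two texts
#'
#' Over the union of scorable words (lexicon words outside the neutral
#' band), each word contributes
#' `delta(w) = (h(w) - h_ref) * (p_comp(w) - p_ref(w))`, where `p` is the
#' word's normalized frequency among the *scorable* words of its text
#' (0 when absent). The contributions sum exactly to
#' `h_comp - h_ref`. Each word is classified `+`/`-` by whether it is
#' happier or sadder than the reference text as a whole, and up/down by
#' whether it is used more or less in the comparison text.
#'
#' Normalizing frequencies over scorable words only is what makes the
#' decomposition exact under the same neutral-band filter as the scores
#' themselves; per-word percentages then sum to 100% of the difference.
#'
#' @param ref_counts,comp_counts Named word-count vectors (see
#'   [word_counts()]) for the reference and comparison texts.
#' @param lexicon A `gh_lexicon`.
#' @param delta Neutral band half-width override.
#' @return A list of class `gh_wordshift`: `words` (a tibble with `word`,
#'   `score`, `p_ref`, `p_comp`, `contribution`, `percent`, `type` in
#'   `{"+up","-up","+down","-down"}`), `h_ref`, `h_comp`, `delta_h`,
#'   `text_size_ref`, `text_size_comp` (scorable word totals). `percent`
#'   is `NA` when `delta_h` is 0.
#' @export
word_shift <- function(ref_counts, comp_counts, lexicon, delta = NULL) {
  delta <- delta %||% attr(lexicon, "neutral_delta") %||% 1
  h_ref <- score_counts(ref_counts, lexicon, delta)
  h_comp <- score_counts(comp_counts, lexicon, delta)
  abort_if(is.na(h_ref), "reference text has no scorable words")
  abort_if(is.na(h_comp), "comparison text has no scorable words")
  norm_freq <- function(counts) {
    keep <- scorable_words(counts, lexicon, delta)
    f <- as.numeric(counts[keep])
    stats::setNames(f / sum(f), names(counts)[keep])
  }
  p_ref <- norm_freq(ref_counts)
  p_comp <- norm_freq(comp_counts)
  words <- sort(union(names(p_ref), names(p_comp)))
  pr <- ifelse(is.na(match(words, names(p_ref))), 0, p_ref[match(words, names(p_ref))])
  pc <- ifelse(is.na(match(words, names(p_comp))), 0, p_comp[match(words, names(p_comp))])
  h <- lexicon$score[match(words, lexicon$word)]
  contribution <- (h - h_ref) * (pc - pr)
  delta_h <- h_comp - h_ref
  # a word exactly at the reference mean contributes nothing; it is grouped
  # with the relatively sad words so "+" always means strictly happier
  type <- paste0(ifelse(h > h_ref, "+", "-"),
                 ifelse(pc >= pr, "up", "down"))
  percent <- if (delta_h != 0) 100 * contribution / delta_h else rep(NA_real_, length(words))
  structure(list(
    words = tibble::tibble(word = words, score = h, p_ref = unname(pr),
                           p_comp = unname(pc),
                           contribution = unname(contribution),
                           percent = unname(percent), type = type),
    h_ref = h_ref, h_comp = h_comp, delta_h = delta_h,
    text_size_ref = sum(ref_counts[scorable_words(ref_counts, lexicon, delta)]),
    text_size_comp = sum(comp_counts[scorable_words(comp_counts, lexicon, delta)])
  ), class = "gh_wordshift")
}

#' @export
print.gh_wordshift <- function(x, ...) {
  cat(sprintf("<gh_wordshift> h_ref = %.4f, h_comp = %.4f, delta_h = %+.4f, %d words\n",
              x$h_ref, x$h_comp, x$delta_h, nrow(x$words)))
  invisible(x)
}

#' Ranked word-shift contributions
#'
#' Orders words by absolute percent contribution (ties alphabetical) and
#' accumulates the signed percents, giving the curve showing how the top
#' contributors combine toward 100% of the happiness difference.
#'
#' @param shift A `gh_wordshift`.
#' @param top_n Number of top words to return (default all).
#' @return A tibble with `rank`, `word`, `type`, `percent`,
#'   `cumulative_percent`.
#' @export
rank_contributions <- function(shift, top_n = Inf) {
  w <- shift$words
  metric <- if (all(is.na(w$percent))) abs(w$contribution) else abs(w$percent)
  ord <- order(-metric, w$word)
  w <- w[ord, , drop = FALSE]
  out <- tibble::tibble(rank = seq_len(nrow(w)), word = w$word, type = w$type,
                        percent = w$percent,
                        cumulative_percent = cumsum(ifelse(is.na(w$percent), 0,
                                                           w$percent)))
  utils::head(out, top_n)
}

#' Balance of the four word-shift types
#'
#' Sums contributions within each of the four classes (relatively happy or
#' sad word, used more or less in the comparison text); the four totals
#' add exactly to the happiness difference.
#'
#' @param shift A `gh_wordshift`.
#' @return A tibble with `type` (`"+up"`, `"-up"`, `"+down"`, `"-down"`)
#'   and `total` (signed contribution sums).
#' @export
type_balance <- function(shift) {
  types <- c("+up", "-up", "+down", "-down")
  total <- vapply(types, function(t) {
    sum(shift$words$contribution[shift$words$type == t])
  }, numeric(1))
  tibble::tibble(type = types, total = unname(total))
}
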