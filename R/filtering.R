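# Quality-control filters: keyword-based bot removal, Foursquare check-in
# tagging, minimum-activity thresholds, and sentiment eligibility. Check-ins
# stay in the mobility corpus; only sentiment analyses drop them.

#' Detect robotic accounts
#'
#' Flags users for whom at least `fraction` of messages contain one of the
#' trigger keywords as a lowercased token (token match, not substring, so
#' 'humid' and 'humidity' are distinct entries). "At least half" is
#' inclusive: exactly half triggers the flag.
#'
#' @param corpus A [corpus()].
#' @param keywords Trigger words; defaults to the weather/traffic/coupon
#'   list characterizing automated feeds.
#' @param fraction Minimum keyword-message fraction (default 0.5).
#' @return Character vector of flagged user ids.
#' @export
detect_bots <- function(corpus, keywords = DEFAULT_BOT_KEYWORDS, fraction = 0.5) {
  if (nrow(corpus) == 0) return(character(0))
  toks <- tokenize(corpus$text)
  hit <- vapply(toks, function(w) any(w %in% keywords), logical(1))
  agg <- tapply(hit, corpus$user_id, mean)
  names(agg)[agg >= fraction]
}

#' Detect Foursquare check-in messages
#'
#' A message is a check-in iff its text contains the Foursquare share-URL
#' marker `4sq.com` (case-insensitive) -- the stable signature of check-in
#' shares, whose phrasing otherwise varies.
#'
#' @param text Character vector of message texts.
#' @return Logical vector.
#' @export
detect_checkin <- function(text) {
  grepl("4sq.com", tolower(text), fixed = TRUE)
}

#' Tag check-ins on a corpus
#'
#' @param corpus A [corpus()].
#' @return The corpus with its `is_checkin` column set.
#' @export
tag_checkins <- function(corpus) {
  corpus$is_checkin <- detect_checkin(corpus$text)
  corpus
}

#' Apply a minimum-activity threshold
#'
#' Keeps users with at least (`strict = FALSE`, the default, as in the
#' 30-message and 800-message thresholds) or strictly more than
#' (`strict = TRUE`, as in the more-than-50-locations population)
#' `min_messages` messages.
#'
#' @param corpus A [corpus()].
#' @param min_messages Threshold (default 30).
#' @param strict Use strict inequality.
#' @return The filtered corpus.
#' @export
apply_activity_threshold <- function(corpus, min_messages = 30, strict = FALSE) {
  if (nrow(corpus) == 0) return(corpus)
  cnt <- table(corpus$user_id)
  keep_users <- names(cnt)[if (strict) cnt > min_messages else cnt >= min_messages]
  out <- corpus[corpus$user_id %in% keep_users, , drop = FALSE]
  out
}

#' Sentiment eligibility of messages
#'
#' A message enters happiness analyses iff it is not a check-in and its
#' author is not a bot. Mobility analyses ignore this flag: check-ins are
#' retained when characterizing movement.
#'
#' @param corpus A [corpus()] (check-ins tagged via [tag_checkins()] or
#'   detected on the fly).
#' @param bot_ids Character vector of bot user ids.
#' @return Logical vector, one element per message.
#' @export
sentiment_eligible <- function(corpus, bot_ids = character(0)) {
  checkin <- if (any(corpus$is_checkin)) corpus$is_checkin else detect_checkin(corpus$text)
  !checkin & !(corpus$user_id %in% bot_ids)
}

#' Run the full quality-control filter
#'
#' Detects bots, tags check-ins, applies the activity threshold, and
#' returns the surviving mobility corpus together with a report. The
#' surviving corpus still contains check-in messages (used for mobility);
#' use [sentiment_eligible()] to drop them for happiness analyses.
#'
#' @param corpus A [corpus()].
#' @param min_messages Activity threshold applied after bot removal.
#' @param keywords,fraction Bot-detection parameters, see [detect_bots()].
#' @return A list of class `gh_filter_report`: `corpus` (surviving),
#'   `bot_user_ids`, `n_checkins`, `n_users_below_threshold`,
#'   `n_messages_removed`.
#' @export
filter_corpus <- function(corpus, min_messages = 30,
                          keywords = DEFAULT_BOT_KEYWORDS, fraction = 0.5) {
  bots <- detect_bots(corpus, keywords, fraction)
  tagged <- tag_checkins(corpus)
  no_bots <- tagged[!tagged$user_id %in% bots, , drop = FALSE]
  out <- apply_activity_threshold(no_bots, min_messages)
  n_below <- length(unique(no_bots$user_id)) - length(unique(out$user_id))
  structure(list(
    corpus = out,
    bot_user_ids = bots,
    n_checkins = sum(out$is_checkin),
    n_users_below_threshold = n_below,
    n_messages_removed = nrow(corpus) - nrow(out)
  ), class = "gh_filter_report")
}

#' @export
print.gh_filter_report <- function(x, ...) {
  cat(sprintf(paste0("<gh_filter_report> %d bots removed, %d users below ",
                     "threshold, %d check-ins tagged, %d messages surviving\n"),
              length(x$bot_user_ids), x$n_users_below_threshold,
              x$n_checkins, nrow(x$corpus)))
  invisible(x)
}
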