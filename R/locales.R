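# Tweet locales: tight, non-overlapping circles (radius <= 100 m) holding
# at least 10 of one user's messages. The definition fixes what a locale is;
# the deterministic construction here is a leader pass in chronological
# order, a reassignment refinement, and greedy acceptance by count.

#' Extract a user's tweet locales
#'
#' Deterministic three-phase construction:
#' 1. *Leader pass* (chronological order): each message joins the nearest
#'    existing candidate whose running-mean center is within `radius_max`,
#'    updating that center, otherwise it opens a new candidate.
#' 2. *Refinement*: repeatedly reassign every message to its nearest
#'    candidate center if within `radius_max` and recompute centers as
#'    member means, until stable or `max_iter` iterations.
#' 3. *Acceptance*: candidates are visited in descending count (ties:
#'    earliest first message); each sets its radius to the maximum member
#'    distance and is accepted iff it holds at least `min_count` messages
#'    and its circle intersects no previously accepted circle.
#'
#' Accepted locales satisfy, by construction: every member within
#' `radius_max` of the center, the center equal to the mean member
#' position, count at least `min_count`, and pairwise disjoint circles.
#'
#' @param lat,lon Message coordinates (one user, chronological order).
#' @param message_id Message ids aligned with the coordinates.
#' @param radius_max Maximum member distance from the center, meters.
#' @param min_count Minimum number of member messages.
#' @param max_iter Refinement iteration cap.
#' @return A list of locales sorted by rank (descending count; ties broken
#'   by earliest first visit). Each locale is a list with `center`
#'   (named `c(lat, lon)`), `radius_m`, `count`, `member_ids`,
#'   `first_time_index` and `rank`.
#' @export
extract_locales <- function(lat, lon, message_id = as.character(seq_along(lat)),
                            radius_max = 100, min_count = 10, max_iter = 20) {
  n <- length(lat)
  if (n == 0) return(list())
  origin <- c((min(lat) + max(lat)) / 2, (min(lon) + max(lon)) / 2)
  pl <- project_local(lat, lon, origin)
  x <- pl$x
  y <- pl$y

  # phase 1: leader pass
  cx <- numeric(0)
  cy <- numeric(0)
  csize <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    if (length(cx) > 0) {
      d2 <- (cx - x[i])^2 + (cy - y[i])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= radius_max) {
        assign[i] <- j
        csize[j] <- csize[j] + 1L
        cx[j] <- cx[j] + (x[i] - cx[j]) / csize[j]
        cy[j] <- cy[j] + (y[i] - cy[j]) / csize[j]
        next
      }
    }
    cx <- c(cx, x[i])
    cy <- c(cy, y[i])
    csize <- c(csize, 1L)
    assign[i] <- length(cx)
  }

  # phase 2: refinement
  for (iter in seq_len(max_iter)) {
    dx <- outer(x, cx, "-")
    dy <- outer(y, cy, "-")
    dmat <- sqrt(dx^2 + dy^2)
    nearest <- max.col(-dmat, ties.method = "first")
    nd <- dmat[cbind(seq_len(n), nearest)]
    new_assign <- ifelse(nd <= radius_max, nearest, 0L)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    keep <- sort(unique(assign[assign > 0]))
    if (length(keep) == 0) break
    remap <- integer(length(cx))
    remap[keep] <- seq_along(keep)
    assign[assign > 0] <- remap[assign[assign > 0]]
    cx <- vapply(keep, function(j) mean(x[assign == remap[j]]), numeric(1))
    cy <- vapply(keep, function(j) mean(y[assign == remap[j]]), numeric(1))
  }

  live <- sort(unique(assign[assign > 0]))
  if (length(live) == 0) return(list())
  cand <- lapply(live, function(j) {
    idx <- which(assign == j)
    # if refinement hit the iteration cap, a member may sit just beyond
    # radius_max of the recomputed mean; trim farthest members until the
    # membership rule holds again, keeping center = mean of members
    repeat {
      ctr_x <- mean(x[idx])
      ctr_y <- mean(y[idx])
      d <- sqrt((x[idx] - ctr_x)^2 + (y[idx] - ctr_y)^2)
      if (length(idx) == 0 || max(d) <= radius_max) break
      idx <- idx[-which.max(d)]
    }
    if (length(idx) == 0) return(NULL)
    list(idx = idx,
         x = ctr_x, y = ctr_y,
         count = length(idx),
         radius = max(sqrt((x[idx] - ctr_x)^2 + (y[idx] - ctr_y)^2)),
         first = min(idx))
  })
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (length(cand) == 0) return(list())

  # phase 3: greedy acceptance, descending count, ties earliest first message
  counts <- vapply(cand, `[[`, integer(1), "count")
  firsts <- vapply(cand, `[[`, numeric(1), "first")
  ord <- order(-counts, firsts)
  accepted <- list()
  for (j in ord) {
    cj <- cand[[j]]
    if (cj$count < min_count) next
    ok <- TRUE
    for (a in accepted) {
      if (sqrt((a$x - cj$x)^2 + (a$y - cj$y)^2) < a$radius + cj$radius) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted[[length(accepted) + 1]] <- cj
  }
  lapply(seq_along(accepted), function(r) {
    a <- accepted[[r]]
    ll <- unproject_local(a$x, a$y, origin)
    list(center = c(lat = ll$lat, lon = ll$lon),
         radius_m = a$radius,
         count = a$count,
         member_ids = message_id[a$idx],
         first_time_index = a$first,
         rank = r)
  })
}

#' Locale visitation profile
#'
#' Attaches visitation probabilities `p_i = count_i / N` to a user's
#' locales, where `N` is the user's total message count. Probabilities are
#' non-increasing in rank and need not sum to one, since messages outside
#' every locale carry the remaining mass.
#'
#' @param locales A locale list from [extract_locales()].
#' @param n_messages The user's total message count `N`.
#' @return A list of class `gh_locale_profile` with `locales`, `rank`,
#'   `probability`, `mode_location` (center of the rank-1 locale, or `NULL`
#'   if no locales) and `n_messages`.
#' @export
locale_probabilities <- function(locales, n_messages) {
  abort_if(n_messages == 0, "locale_probabilities: N must be positive")
  counts <- vapply(locales, `[[`, integer(1), "count")
  abort_if(sum(counts) > n_messages,
           "locale membership exceeds the user's message count")
  structure(list(
    locales = locales,
    rank = seq_along(locales),
    probability = if (length(counts)) counts / n_messages else numeric(0),
    mode_location = if (length(locales)) locales[[1]]$center else NULL,
    n_messages = n_messages
  ), class = "gh_locale_profile")
}

#' Mode location of a profile
#'
#' @param profile A `gh_locale_profile`.
#' @return Named `c(lat, lon)` of the rank-1 locale center, or `NULL` when
#'   the user has no locales (such users are excluded from mode analyses).
#' @export
mode_location <- function(profile) {
  profile$mode_location
}

#' Locale profiles for a whole corpus
#'
#' @param corpus A [corpus()].
#' @param radius_max,min_count Locale parameters, see [extract_locales()].
#' @return A named list of `gh_locale_profile`, one per user.
#' @export
locale_profiles <- function(corpus, radius_max = 100, min_count = 10) {
  per_user <- split_users(corpus)
  out <- lapply(per_user, function(u) {
    locs <- extract_locales(u$lat, u$lon, u$message_id,
                            radius_max = radius_max, min_count = min_count)
    locale_probabilities(locs, nrow(u))
  })
  names(out) <- names(per_user)
  out
}

#' Pooled rank-probability table
#'
#' @param profiles A list of `gh_locale_profile` (e.g. [locale_profiles()]).
#' @return A tibble with `user_id`, `rank`, `probability`, pooled over users;
#'   one row per (user, locale).
#' @export
rank_probability_table <- function(profiles) {
  rows <- lapply(names(profiles), function(uid) {
    p <- profiles[[uid]]
    if (length(p$rank) == 0) return(NULL)
    tibble::tibble(user_id = uid, rank = p$rank, probability = p$probability)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble::tibble(user_id = character(), rank = integer(),
                          probability = numeric()))
  }
  do.call(rbind, rows)
}

#' Fit the Zipf rank-probability law
#'
#' Ordinary least squares of `log10(probability)` on `log10(rank)` over all
#' pooled (rank, probability) points. For locale visitation the expected
#' slope is about -1.3: steeper than the classic Zipf exponent of 1, so
#' visitation probability falls off faster than `1/rank`.
#'
#' @param rank,probability Pooled rank-probability pairs (probability > 0).
#' @return A list with `slope`, `intercept`, `se_slope`, `r_squared`, `n`.
#' @export
fit_zipf <- function(rank, probability) {
  keep <- probability > 0
  rank <- rank[keep]
  probability <- probability[keep]
  abort_if(length(unique(rank)) < 2,
           "fit_zipf needs at least 2 distinct ranks with positive probability")
  fit <- stats::lm(log10(probability) ~ log10(rank))
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se_slope = s$coefficients[2, 2],
       r_squared = s$r.squared,
       n = length(rank))
}

#' Diurnal week profiles of mode-locale vs other messages
#'
#' Distributes messages over the 168 local week-hours (Monday 00:00 through
#' Sunday 23:00) separately for messages sent from their author's mode
#' locale and for all other messages; each curve sums to 1. Messages
#' without a local offset, and users without a mode locale, are excluded.
#'
#' @param corpus A [corpus()].
#' @param profiles Named list of `gh_locale_profile` keyed by user id.
#' @return A tibble with `week_hour` (0-167), `p_mode`, `p_other`. Either
#'   column is `NA` if its curve has no eligible messages.
#' @export
diurnal_profiles <- function(corpus, profiles) {
  m <- tibble::as_tibble(corpus)
  m <- m[!is.na(m$utc_offset_min), , drop = FALSE]
  mode_ids <- unlist(lapply(profiles, function(p) {
    if (length(p$locales) > 0) p$locales[[1]]$member_ids else character(0)
  }), use.names = FALSE)
  has_mode <- names(profiles)[vapply(profiles, function(p) length(p$locales) > 0,
                                     logical(1))]
  m <- m[m$user_id %in% has_mode, , drop = FALSE]
  local_time <- m$time_utc + 60 * m$utc_offset_min
  # week hour: Monday 00:00 -> 0, Sunday 23:00 -> 167
  wday <- (as.POSIXlt(local_time, tz = "UTC")$wday + 6L) %% 7L
  hour <- as.POSIXlt(local_time, tz = "UTC")$hour
  wh <- wday * 24L + hour
  is_mode <- m$message_id %in% mode_ids
  curve <- function(sel) {
    if (!any(sel)) return(rep(NA_real_, 168))
    tabulate(wh[sel] + 1L, nbins = 168) / sum(sel)
  }
  tibble::tibble(week_hour = 0:167,
                 p_mode = curve(is_mode),
                 p_other = curve(!is_mode))
}
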