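# Seeded synthetic message populations with exposed ground truth. The
# generator emulates the statistical structure the analysis assumes:
# per-user home/work locale systems visited with Zipf-distributed
# probabilities, GPS noise at the 10 m scale, diurnal cycles concentrated
# at the mode locale in the morning and evening, occasional long-range
# excursion episodes, bot and check-in contamination, and vocabulary whose
# filtered mean happiness follows a dip-then-logarithmic-rise profile in
# distance from the user's (realized) expected location.

DEFAULT_BOT_KEYWORDS <- c("pressure", "humid", "humidity", "earthquake",
                          "traffic", "coupon")

# local-hour sampling weights; mode locale peaks in the morning (8-10) and
# evening (10pm-midnight), with the morning peak higher and the afternoon
# valley lower than the overnight one
MODE_HOUR_WEIGHTS <- c(1.0, 0.7, 0.5, 0.5, 0.5, 0.7, 1.2, 2.0, 3.2, 3.2,
                       3.0, 1.8, 1.2, 0.8, 0.4, 0.4, 0.4, 0.8, 1.2, 1.5,
                       1.8, 2.2, 2.6, 2.6)
OTHER_HOUR_WEIGHTS <- c(0.8, 0.6, 0.5, 0.5, 0.5, 0.6, 0.8, 1.0, 1.2, 1.4,
                        1.6, 1.8, 2.0, 2.0, 2.0, 1.9, 1.8, 1.8, 1.7, 1.6,
                        1.4, 1.2, 1.0, 0.9)

#' Synthetic population configuration
#'
#' Returns the full parameter set of the synthetic-population generator.
#' The defaults describe the standard study population; see
#' `heavy = TRUE` for the heavy-user population (the ~300 individuals with
#' on the order of 900 geolocated messages each) used for locale rank
#' analyses.
#'
#' @param n_individuals Number of individuals (default 3000 standard,
#'   300 heavy).
#' @param heavy If `TRUE`, switch the message-count distribution to the
#'   heavy-user regime (lognormal median 900) and default `n_individuals`
#'   to 300.
#' @param ... Overrides for any configuration field (validated by name).
#' @return A list of class `gh_popconfig`.
#' @section Fields:
#' * `msgs_median`, `msgs_sdlog`: per-user message count, lognormal
#'   (median 60 standard / 900 heavy).
#' * `locales_min`, `locales_max`: locales per user, uniform 3-15.
#' * `zipf_exponent`: locale visitation exponent `s` (1.3).
#' * `locale_fraction`: fraction of non-excursion messages posted from a
#'   locale (0.8); the remainder scatter uniformly within 3 commute-scale
#'   gyradii of the locale-system mean.
#' * `homework_sep_median_m`, `homework_sep_sdlog`: home-work separation,
#'   lognormal median 3 km.
#' * `gps_noise_sigma_m`: isotropic GPS noise (5 m, so ~95% of positions
#'   fall inside a 10 m circle).
#' * `excursion_init_p`, `excursion_mean_len`, `excursion_dist_median_m`,
#'   `excursion_dist_sdlog`, `excursion_jitter_m`, `excursion_max_m`:
#'   long-range excursion episodes: each message starts one with
#'   probability 0.01; an episode covers a geometric number of messages
#'   (mean 20) posted near a destination drawn lognormally (median 500 km,
#'   capped below the antipode).
#' * `happiness_alpha`, `happiness_beta`, `d_dip_m`, `h_dip`, `d_floor_m`:
#'   expected filtered word happiness versus distance `d` from the
#'   realized expected location:
#'   `mu(d) = h_dip + beta * log10(d / d_dip)` beyond the dip at
#'   `d_dip` = 10 km, and a shallow rise toward home,
#'   `mu(d) = h_dip + alpha * log10(d_dip / max(d, d_floor))`, below it.
#' * `words_per_msg_mean`, `neutral_word_p`: message length (1 + Poisson)
#'   and the share of neutral filler words.
#' * `bot_fraction`, `checkin_fraction`: contamination rates.
#' * `bot_keywords`: token list characterizing robotic accounts.
#' * `lat_range`, `lon_range`: home-base region (continental-US-like).
#' * `utc_offsets_min`: per-user local offsets sampled from
#'   `{-8, -7, -6, -5}` hours.
#' * `mode_hour_weights`, `other_hour_weights`: 24 local-hour sampling
#'   weights for mode-locale and other messages.
#' @export
population_config <- function(n_individuals = if (heavy) 300 else 3000,
                              heavy = FALSE, ...) {
  cfg <- list(
    n_individuals = n_individuals,
    msgs_median = if (heavy) 900 else 60,
    msgs_sdlog = if (heavy) 0.25 else 0.5,
    locales_min = 3L,
    locales_max = 15L,
    zipf_exponent = 1.3,
    locale_fraction = 0.8,
    homework_sep_median_m = 3000,
    homework_sep_sdlog = 0.6,
    gps_noise_sigma_m = 5,
    excursion_init_p = 0.01,
    excursion_mean_len = 20,
    excursion_dist_median_m = 5e5,
    excursion_dist_sdlog = 2.0,
    excursion_jitter_m = 2000,
    excursion_max_m = 1.9e7,
    happiness_alpha = 0.0495,
    happiness_beta = 0.1,
    d_dip_m = 1e4,
    h_dip = 6.13 - 0.1 * log10(2.5e6 / 1e4),
    d_floor_m = 30,
    words_per_msg_mean = 8,
    neutral_word_p = 0.3,
    bot_fraction = 0.02,
    checkin_fraction = 0.05,
    bot_keywords = DEFAULT_BOT_KEYWORDS,
    lat_range = c(33, 45),
    lon_range = c(-118, -75),
    utc_offsets_min = c(-480L, -420L, -360L, -300L),
    mode_hour_weights = MODE_HOUR_WEIGHTS,
    other_hour_weights = OTHER_HOUR_WEIGHTS,
    city_pair_rho = 0.24
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  abort_if(length(bad) > 0, "unknown population_config field(s): %s",
           paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  class(cfg) <- "gh_popconfig"
  cfg
}

validate_config <- function(cfg) {
  chk01 <- function(f) abort_if(cfg[[f]] < 0 || cfg[[f]] > 1,
                                "population_config: '%s' must be in [0, 1]", f)
  for (f in c("locale_fraction", "excursion_init_p", "bot_fraction",
              "checkin_fraction", "neutral_word_p")) chk01(f)
  abort_if(cfg$zipf_exponent <= 0, "population_config: 'zipf_exponent' must be > 0")
  abort_if(cfg$n_individuals < 0, "population_config: 'n_individuals' must be >= 0")
  abort_if(cfg$locales_min < 1 || cfg$locales_max < cfg$locales_min,
           "population_config: invalid 'locales_min'/'locales_max'")
  abort_if(length(cfg$mode_hour_weights) != 24 ||
             length(cfg$other_hour_weights) != 24,
           "population_config: hour weight vectors must have length 24")
  invisible(cfg)
}

#' Expected filtered happiness at a distance
#'
#' The generator's ground-truth happiness profile `mu(d)`: a shallow local
#' maximum near home, a minimum (`h_dip`) at commute scale `d_dip`, then a
#' logarithmic increase with distance. With the default calibration
#' `mu(2500 km) = 6.13` and the nearest-decile distance of the default
#' population scores 5.96.
#'
#' @param config A [population_config()].
#' @param d Distance(s) from the expected location, meters, > 0.
#' @return Expected filtered mean word happiness at each distance.
#' @export
truth_happiness_at <- function(config, d) {
  abort_if(any(d <= 0), "truth_happiness_at: distances must be positive")
  below <- config$h_dip + config$happiness_alpha *
    log10(config$d_dip_m / pmax(d, config$d_floor_m))
  above <- config$h_dip + config$happiness_beta * log10(d / config$d_dip_m)
  ifelse(d > config$d_dip_m, above, below)
}

# word pools drawn from the packaged example lexicon: positive-enriched
# far-from-home vocabulary vs negative-enriched near-home vocabulary
happiness_pools <- function() {
  lex <- read_lexicon(example_lexicon_path())
  pos <- lex$word[lex$score >= 6]
  neg <- lex$word[lex$score <= 4]
  neu <- lex$word[lex$score > 4 & lex$score < 6]
  list(pos = pos, neg = neg, neu = neu,
       m_pos = mean(lex$score[lex$score >= 6]),
       m_neg = mean(lex$score[lex$score <= 4]))
}

#' Generate a synthetic population
#'
#' Emits a message corpus plus the ground truth that produced it. All
#' randomness flows through `seed`; the same `(config, seed)` pair yields
#' a byte-identical corpus.
#'
#' @param config A [population_config()].
#' @param seed Integer seed (mandatory).
#' @param include_text If `FALSE`, message texts are empty strings (faster
#'   when only geometry is needed).
#' @return A list with `corpus` (a [corpus()]) and `truth`, a list holding
#'   `users` (tibble: `user_id`, `is_bot`, `n_messages`, `n_locales`,
#'   `sep_m`, `home_lat`, `home_lon`, `rg_locale_m`, `utc_offset_min`,
#'   plus list-columns `locale_lat`, `locale_lon`, `visit_prob`),
#'   `bot_ids`, `checkin_ids`, and the generating `config`.
#' @export
generate_population <- function(config, seed, include_text = TRUE) {
  abort_if(missing(seed) || !is.numeric(seed), "generate_population requires a seed")
  with_seed(seed, generate_population_impl(config, include_text))
}

generate_population_impl <- function(config, include_text) {
  n <- config$n_individuals
  if (n == 0) {
    return(list(corpus = empty_corpus(),
                truth = list(users = tibble::tibble(), bot_ids = character(0),
                             checkin_ids = character(0), config = config)))
  }
  pools <- if (include_text) happiness_pools() else NULL
  n_bots <- round(config$bot_fraction * n)
  is_bot <- rep(FALSE, n)
  if (n_bots > 0) is_bot[sample.int(n, n_bots)] <- TRUE

  msg_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  msg_counter <- 0L
  for (u in seq_len(n)) {
    uid <- sprintf("u%05d", u)
    N <- max(5L, as.integer(round(stats::rlnorm(1, log(config$msgs_median),
                                                config$msgs_sdlog))))
    offset <- sample(config$utc_offsets_min, 1)
    home <- c(stats::runif(1, config$lat_range[1], config$lat_range[2]),
              stats::runif(1, config$lon_range[1], config$lon_range[2]))
    if (is_bot[u]) {
      g <- generate_bot_user(uid, N, home, offset, config, msg_counter)
    } else {
      g <- generate_regular_user(uid, N, home, offset, config, pools,
                                 include_text, msg_counter)
    }
    msg_counter <- msg_counter + N
    msg_rows[[u]] <- g$messages
    truth_rows[[u]] <- g$truth
  }
  msgs <- do.call(rbind, msg_rows)
  truth_users <- do.call(rbind, truth_rows)
  # check-in contamination on non-bot messages
  checkin_ids <- character(0)
  if (config$checkin_fraction > 0) {
    eligible <- which(!msgs$user_id %in% truth_users$user_id[truth_users$is_bot])
    take <- eligible[stats::runif(length(eligible)) < config$checkin_fraction]
    if (length(take) > 0) {
      tags <- sprintf(" i'm at somewhere http://4sq.com/%s",
                      vapply(take, function(i)
                        paste(sample(letters, 6, TRUE), collapse = ""),
                        character(1)))
      msgs$text[take] <- paste0(msgs$text[take], tags)
      checkin_ids <- msgs$message_id[take]
    }
  }
  list(corpus = corpus(msgs),
       truth = list(users = truth_users,
                    bot_ids = truth_users$user_id[truth_users$is_bot],
                    checkin_ids = checkin_ids,
                    config = config))
}

# locale centers in a planar frame (meters) around the home base:
# home at the origin, work at the sampled separation, minor locales
# scattered isotropically at the separation scale, all >= 250 m apart
sample_locale_centers <- function(K, sep) {
  th <- stats::runif(1, 0, 2 * pi)
  centers <- rbind(c(0, 0), sep * c(cos(th), sin(th)))
  while (nrow(centers) < K) {
    for (try in 1:50) {
      cand <- stats::rnorm(2, 0, sep)
      d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (all(d >= 250)) break
    }
    centers <- rbind(centers, cand)
  }
  centers
}

# excursion-episode indicator over N chronologically ordered messages
episode_kinds <- function(N, init_p, mean_len) {
  kind <- logical(N)
  i <- 1L
  while (i <= N) {
    if (stats::runif(1) < init_p) {
      len <- 1L + stats::rgeom(1, 1 / mean_len)
      kind[i:min(N, i + len - 1L)] <- TRUE
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  kind
}

sample_times <- function(N, is_mode, config) {
  day <- sample.int(365L, N, replace = TRUE) - 1L
  w_mode <- config$mode_hour_weights / sum(config$mode_hour_weights)
  w_other <- config$other_hour_weights / sum(config$other_hour_weights)
  hour <- integer(N)
  n_mode <- sum(is_mode)
  if (n_mode > 0) hour[is_mode] <- sample.int(24L, n_mode, TRUE, w_mode) - 1L
  if (n_mode < N) hour[!is_mode] <- sample.int(24L, N - n_mode, TRUE, w_other) - 1L
  secs <- sample.int(3600L, N, replace = TRUE) - 1L
  as.POSIXct("2011-01-01 00:00:00", tz = "UTC") +
    day * 86400 + hour * 3600 + secs
}

generate_regular_user <- function(uid, N, home, offset, config, pools,
                                  include_text, msg_counter) {
  K <- sample(seq(config$locales_min, config$locales_max), 1)
  sep <- stats::rlnorm(1, log(config$homework_sep_median_m),
                       config$homework_sep_sdlog)
  centers <- sample_locale_centers(K, sep)
  pz <- seq_len(K)^(-config$zipf_exponent)
  pz <- pz / sum(pz)
  mu_loc <- colSums(pz * centers)
  rg_loc <- sqrt(sum(pz * ((centers[, 1] - mu_loc[1])^2 +
                             (centers[, 2] - mu_loc[2])^2)))
  rg_loc <- max(rg_loc, 100)

  exc <- episode_kinds(N, config$excursion_init_p, config$excursion_mean_len)
  x <- numeric(N)
  y <- numeric(N)
  locale_idx <- rep(NA_integer_, N)
  reg <- which(!exc)
  in_loc <- reg[stats::runif(length(reg)) < config$locale_fraction]
  sc <- setdiff(reg, in_loc)
  if (length(in_loc) > 0) {
    li <- sample.int(K, length(in_loc), TRUE, pz)
    locale_idx[in_loc] <- li
    x[in_loc] <- centers[li, 1]
    y[in_loc] <- centers[li, 2]
  }
  if (length(sc) > 0) {
    rr <- 3 * rg_loc * sqrt(stats::runif(length(sc)))
    aa <- stats::runif(length(sc), 0, 2 * pi)
    x[sc] <- mu_loc[1] + rr * cos(aa)
    y[sc] <- mu_loc[2] + rr * sin(aa)
  }
  iexc <- which(exc)
  if (length(iexc) > 0) {
    runs <- split(iexc, cumsum(c(1, diff(iexc) != 1)))
    for (run in runs) {
      d <- min(stats::rlnorm(1, log(config$excursion_dist_median_m),
                             config$excursion_dist_sdlog),
               config$excursion_max_m)
      a <- stats::runif(1, 0, 2 * pi)
      x[run] <- d * cos(a) + stats::rnorm(length(run), 0, config$excursion_jitter_m)
      y[run] <- d * sin(a) + stats::rnorm(length(run), 0, config$excursion_jitter_m)
    }
  }
  x <- x + stats::rnorm(N, 0, config$gps_noise_sigma_m)
  y <- y + stats::rnorm(N, 0, config$gps_noise_sigma_m)
  ll <- unproject_local(x, y, home)

  text <- rep("", N)
  if (include_text) {
    dctr <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    mu_d <- truth_happiness_at(config, pmax(dctr, 1))
    q <- (mu_d - pools$m_neg) / (pools$m_pos - pools$m_neg)
    q <- pmin(1, pmax(0, q))
    n_tok <- 1L + stats::rpois(N, config$words_per_msg_mean - 1)
    tok_msg <- rep.int(seq_len(N), n_tok)
    n_all <- sum(n_tok)
    is_neu <- stats::runif(n_all) < config$neutral_word_p
    is_pos <- stats::runif(n_all) < q[tok_msg]
    words <- character(n_all)
    words[is_neu] <- sample(pools$neu, sum(is_neu), TRUE)
    pos_sel <- !is_neu & is_pos
    neg_sel <- !is_neu & !is_pos
    words[pos_sel] <- sample(pools$pos, sum(pos_sel), TRUE)
    words[neg_sel] <- sample(pools$neg, sum(neg_sel), TRUE)
    text <- vapply(split(words, tok_msg), paste, character(1), collapse = " ")
    text <- unname(text[as.character(seq_len(N))])
  }

  is_mode <- !is.na(locale_idx) & locale_idx == 1L
  time_local <- sample_times(N, is_mode, config)
  time_utc <- time_local - 60 * offset
  ord <- order(time_utc)

  ctr_ll <- unproject_local(centers[, 1], centers[, 2], home)
  msgs <- tibble::tibble(
    user_id = uid,
    message_id = sprintf("m%08d", msg_counter + seq_len(N)),
    time_utc = time_utc[ord],
    utc_offset_min = offset,
    lat = ll$lat[ord],
    lon = ll$lon[ord],
    text = text[ord]
  )
  truth <- tibble::tibble(
    user_id = uid, is_bot = FALSE, n_messages = N, n_locales = K,
    sep_m = sep, home_lat = home[1], home_lon = home[2],
    rg_locale_m = rg_loc, utc_offset_min = offset,
    locale_lat = list(ctr_ll$lat), locale_lon = list(ctr_ll$lon),
    # unconditional visitation probability: in-locale fraction discounted by
    # the expected share of messages spent on excursion episodes
    visit_prob = list(config$locale_fraction * pz /
                        (1 + config$excursion_init_p * config$excursion_mean_len))
  )
  list(messages = msgs, truth = truth)
}

generate_bot_user <- function(uid, N, home, offset, config, msg_counter) {
  # stationary robotic account; every message carries a trigger keyword
  x <- stats::rnorm(N, 0, config$gps_noise_sigma_m)
  y <- stats::rnorm(N, 0, config$gps_noise_sigma_m)
  ll <- unproject_local(x, y, home)
  kw <- sample(config$bot_keywords, N, TRUE)
  text <- sprintf("%s update number %d", kw, seq_len(N))
  time_utc <- sample_times(N, rep(FALSE, N), config) - 60 * offset
  ord <- order(time_utc)
  msgs <- tibble::tibble(
    user_id = uid,
    message_id = sprintf("m%08d", msg_counter + seq_len(N)),
    time_utc = time_utc[ord],
    utc_offset_min = offset,
    lat = ll$lat[ord], lon = ll$lon[ord],
    text = text[ord]
  )
  truth <- tibble::tibble(
    user_id = uid, is_bot = TRUE, n_messages = N, n_locales = NA_integer_,
    sep_m = NA_real_, home_lat = home[1], home_lon = home[2],
    rg_locale_m = NA_real_, utc_offset_min = offset,
    locale_lat = list(numeric(0)), locale_lon = list(numeric(0)),
    visit_prob = list(numeric(0))
  )
  list(messages = msgs, truth = truth)
}

#' Generate correlated value pairs
#'
#' Draws `n` pairs from a bivariate Gaussian with the given population
#' correlation; stands in for city-level (mean gyradius, land area) pairs
#' in correlation-recovery simulations.
#'
#' @param n Number of pairs (>= 3).
#' @param rho Population correlation in (-1, 1); default the city-level
#'   correlation 0.24.
#' @param seed Integer seed.
#' @return A tibble with columns `x` and `y`.
#' @export
generate_correlated_pairs <- function(n, rho = 0.24, seed) {
  abort_if(n < 3, "generate_correlated_pairs needs n >= 3")
  abort_if(abs(rho) >= 1, "rho must lie strictly inside (-1, 1)")
  abort_if(missing(seed) || !is.numeric(seed), "generate_correlated_pairs requires a seed")
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    tibble::tibble(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
  })
}
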