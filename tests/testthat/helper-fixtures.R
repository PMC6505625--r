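# Shared fixtures, built in code. Expensive synthetic populations are
# generated once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

table1_lexicon <- function(delta = 1) {
  read_lexicon(example_lexicon_path(), neutral_delta = delta)
}

# the heavy-user population: ~300 individuals with on the order of 900
# messages each, used for locale rank analyses
heavy_population <- function() {
  cached("heavy_pop", generate_population(
    population_config(heavy = TRUE, bot_fraction = 0, checkin_fraction = 0),
    seed = 42, include_text = FALSE))
}

heavy_profiles <- function() {
  cached("heavy_profiles", locale_profiles(heavy_population()$corpus))
}

# the standard population with texts, used for happiness trends
standard_population <- function() {
  cached("std_pop", generate_population(population_config(), seed = 7))
}

# small corpus builder: one user at fixed coordinates
make_user_corpus <- function(user_id, lat, lon,
                             text = rep("hello", length(lat)),
                             t0 = as.POSIXct("2011-06-01 12:00:00", tz = "UTC"),
                             offset = -300L, id_prefix = user_id) {
  n <- length(lat)
  tibble::tibble(
    user_id = user_id,
    message_id = sprintf("%s_%04d", id_prefix, seq_len(n)),
    time_utc = t0 + seq_len(n) * 60,
    utc_offset_min = offset,
    lat = lat, lon = lon, text = text)
}

# cluster of n points around a center with given sd (meters), as lat/lon
cluster_latlon <- function(center_lat, center_lon, n, sd_m = 5) {
  x <- stats::rnorm(n, 0, sd_m)
  y <- stats::rnorm(n, 0, sd_m)
  ll <- unproject_local(x, y, c(center_lat, center_lon))
  list(lat = ll$lat, lon = ll$lon)
}
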