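# Pipeline orchestration: composable stages (generate, filter, mobility,
# trajnorm, locales, happiness, wordshift) writing plain CSV tables plus a
# JSON manifest per stage, and a one-shot report. Stage outputs are plain
# text so runs can be inspected and diffed.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: activity
#' threshold 30 messages, locale radius 100 m and minimum count 10,
#' neutral band half-width 1, 10 equal-count bins, heavy-user threshold
#' 800, density-map population threshold of more than 50 locations.
#'
#' @param out_dir Output directory for stage tables and manifests.
#' @param lexicon_path Lexicon file (default: the packaged example lexicon).
#' @param seed Seed for the generate stage.
#' @param ... Overrides for any listed field.
#' @return A list of class `gh_pipeconfig`.
#' @export
pipeline_config <- function(out_dir = tempfile("geohedon_run_"),
                            lexicon_path = example_lexicon_path(),
                            seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    lexicon_path = lexicon_path,
    seed = seed,
    population = population_config(n_individuals = 500),
    min_messages = 30,
    density_min_locations = 50,
    heavy_threshold = 800,
    locale_radius_m = 100,
    locale_min_count = 10,
    neutral_delta = 1,
    bins = 10,
    bot_fraction_threshold = 0.5,
    bot_keywords = DEFAULT_BOT_KEYWORDS
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  abort_if(length(bad) > 0, "unknown pipeline_config field(s): %s",
           paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "gh_pipeconfig"
  cfg
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

write_manifest <- function(config, stage, params, inputs, outputs) {
  manifest <- list(stage = stage, params = params, inputs = inputs,
                   outputs = outputs, seed = config$seed)
  jsonlite::write_json(manifest, stage_path(config, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Stages: `generate`, `filter`, `mobility`, `trajnorm`, `locales`,
#' `happiness`, `wordshift`, or `report` (all of them in order). Each
#' stage reads its upstream artifacts from `config$out_dir`, fails with
#' the missing artifact's name if an upstream stage has not run, and
#' writes CSV tables plus a `*_manifest.json` recording inputs,
#' parameters and seed. Reruns with identical inputs and config are
#' byte-identical.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of files written.
#' @export
run_stage <- function(stage = c("generate", "filter", "mobility", "trajnorm",
                                "locales", "happiness", "wordshift", "report"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "report") {
    files <- unlist(lapply(c("generate", "filter", "mobility", "trajnorm",
                             "locales", "happiness", "wordshift"),
                           run_stage, config = config))
    return(invisible(files))
  }
  need <- function(path, from) {
    abort_if(!file.exists(path),
             "stage '%s' needs missing artifact '%s' (run stage '%s' first)",
             stage, path, from)
    path
  }
  files <- switch(stage,
    generate = {
      gen <- generate_population(config$population, config$seed)
      corpus_path <- stage_path(config, "corpus.jsonl")
      write_messages(gen$corpus, corpus_path)
      tu <- gen$truth$users
      if (nrow(tu) > 0) {
        tu <- tu[, c("user_id", "is_bot", "n_messages", "n_locales",
                     "sep_m", "rg_locale_m")]
      }
      write_table(tu, stage_path(config, "truth_users.csv"))
      c(corpus_path, stage_path(config, "truth_users.csv"))
    },
    filter = {
      cp <- read_messages(need(stage_path(config, "corpus.jsonl"), "generate"),
                          quiet = TRUE)
      rep <- filter_corpus(cp, config$min_messages, config$bot_keywords,
                           config$bot_fraction_threshold)
      write_messages(rep$corpus, stage_path(config, "filtered.jsonl"))
      write_table(tibble::tibble(
        n_bots = length(rep$bot_user_ids),
        n_checkins = rep$n_checkins,
        n_users_below_threshold = rep$n_users_below_threshold,
        n_messages_surviving = nrow(rep$corpus)),
        stage_path(config, "filter_report.csv"))
      c(stage_path(config, "filtered.jsonl"), stage_path(config, "filter_report.csv"))
    },
    mobility = {
      cp <- read_messages(need(stage_path(config, "filtered.jsonl"), "filter"),
                          quiet = TRUE)
      mt <- mobility_table(cp)
      write_table(mt$users, stage_path(config, "mobility_users.csv"))
      write_table(mt$messages, stage_path(config, "message_distances.csv"))
      write_table(gyradius_ccdf(mt$users$gyradius_m),
                  stage_path(config, "gyradius_ccdf.csv"))
      c(stage_path(config, "mobility_users.csv"),
        stage_path(config, "message_distances.csv"),
        stage_path(config, "gyradius_ccdf.csv"))
    },
    trajnorm = {
      cp <- read_messages(need(stage_path(config, "filtered.jsonl"), "filter"),
                          quiet = TRUE)
      cp <- apply_activity_threshold(cp, config$density_min_locations, strict = TRUE)
      nc <- normalize_corpus(cp, min_locations = config$density_min_locations + 1,
                             locale_radius_m = config$locale_radius_m,
                             locale_min_count = config$locale_min_count)
      dm <- density_map(nc$points$x, nc$points$y)
      write_table(dm$grid, stage_path(config, "density_grid.csv"))
      write_table(corridor_profile(nc$points$x, nc$points$y),
                  stage_path(config, "corridor_profile.csv"))
      gy <- vapply(split_users(cp)[names(nc$trajectories)], function(u)
        gyradius(u$lat, u$lon), numeric(1))
      if (length(nc$trajectories) >= 10) {
        write_table(isotropy_by_gyradius(nc$trajectories, gy),
                    stage_path(config, "isotropy_by_decile.csv"))
      }
      stage_path(config, c("density_grid.csv", "corridor_profile.csv"))
    },
    locales = {
      cp <- read_messages(need(stage_path(config, "filtered.jsonl"), "filter"),
                          quiet = TRUE)
      heavy <- apply_activity_threshold(cp, config$heavy_threshold)
      profiles <- locale_profiles(heavy, config$locale_radius_m,
                                  config$locale_min_count)
      rp <- rank_probability_table(profiles)
      write_table(rp, stage_path(config, "rank_probability.csv"))
      if (length(unique(rp$rank)) >= 2) {
        zf <- fit_zipf(rp$rank, rp$probability)
        write_table(tibble::as_tibble(zf[c("slope", "intercept", "se_slope",
                                           "r_squared", "n")]),
                    stage_path(config, "zipf_fit.csv"))
      }
      write_table(diurnal_profiles(heavy, profiles),
                  stage_path(config, "diurnal_profiles.csv"))
      stage_path(config, c("rank_probability.csv", "diurnal_profiles.csv"))
    },
    happiness = {
      lex <- read_lexicon(need(config$lexicon_path, "none"),
                          neutral_delta = config$neutral_delta)
      cp <- read_messages(need(stage_path(config, "filtered.jsonl"), "filter"),
                          quiet = TRUE)
      dist <- read_table(need(stage_path(config, "message_distances.csv"),
                              "mobility"))
      cp <- tag_checkins(cp)
      elig <- sentiment_eligible(cp)
      m <- cp[elig, , drop = FALSE]
      d <- dist$distance_m[match(m$message_id, dist$message_id)]
      trend <- happiness_by_distance(m$text, d, lex, k = config$bins)
      write_table(trend, stage_path(config, "happiness_by_distance.csv"))
      mu <- read_table(need(stage_path(config, "mobility_users.csv"), "mobility"))
      gy <- stats::setNames(mu$gyradius_m, mu$user_id)
      trend_g <- happiness_by_gyradius(m$text, m$user_id, gy, lex,
                                       k = config$bins)
      write_table(trend_g, stage_path(config, "happiness_by_gyradius.csv"))
      stage_path(config, c("happiness_by_distance.csv", "happiness_by_gyradius.csv"))
    },
    wordshift = {
      lex <- read_lexicon(need(config$lexicon_path, "none"),
                          neutral_delta = config$neutral_delta)
      cp <- read_messages(need(stage_path(config, "filtered.jsonl"), "filter"),
                          quiet = TRUE)
      dist <- read_table(need(stage_path(config, "message_distances.csv"),
                              "mobility"))
      cp <- tag_checkins(cp)
      m <- cp[sentiment_eligible(cp), , drop = FALSE]
      d <- dist$distance_m[match(m$message_id, dist$message_id)]
      bins <- equal_count_bins(d, config$bins)
      ref <- word_counts(m$text[bins == 1], lex)
      comp <- word_counts(m$text[bins == config$bins], lex)
      ws <- word_shift(ref, comp, lex)
      write_table(rank_contributions(ws), stage_path(config, "wordshift_ranked.csv"))
      write_table(type_balance(ws), stage_path(config, "wordshift_balance.csv"))
      stage_path(config, c("wordshift_ranked.csv", "wordshift_balance.csv"))
    })
  write_manifest(config, stage,
                 params = config[setdiff(names(config), c("population"))],
                 inputs = setdiff(list.files(config$out_dir, full.names = TRUE),
                                  files),
                 outputs = files)
  invisible(files)
}

#' Run the full pipeline
#'
#' Convenience wrapper for `run_stage("report", config)`: generate,
#' filter, mobility, trajnorm, locales, happiness and wordshift in order.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, all files written.
#' @export
run_report <- function(config = pipeline_config()) {
  run_stage("report", config)
}
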