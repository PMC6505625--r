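test_that("locale acceptance boundaries: 10 coincident messages form one locale, 9 do not", {
  ll10 <- cluster_latlon(40, -74, 10, sd_m = 0)
  locs <- extract_locales(ll10$lat, ll10$lon)
  expect_length(locs, 1)
  expect_equal(locs[[1]]$count, 10)
  expect_equal(locs[[1]]$radius_m, 0, tolerance = 1e-9)

  ll9 <- cluster_latlon(40, -74, 9, sd_m = 0)
  expect_length(extract_locales(ll9$lat, ll9$lon), 0)
  expect_length(extract_locales(numeric(0), numeric(0)), 0)
})

test_that("two tight clusters 1 km apart give two locales with exact memberships", {
  withr::with_seed(101, {
    a <- cluster_latlon(40, -74, 15, sd_m = 5)
    b <- cluster_latlon(40.009, -74, 15, sd_m = 5)  # ~1 km north
  })
  lat <- c(a$lat, b$lat)
  lon <- c(a$lon, b$lon)
  ids <- sprintf("m%02d", 1:30)
  locs <- extract_locales(lat, lon, ids)
  expect_length(locs, 2)
  got <- lapply(locs, `[[`, "member_ids")
  expect_setequal(got[[which.min(vapply(locs, function(l) l$center[["lat"]], 1))]],
                  ids[1:15])
  # brute-force oracle: each message belongs to the nearer accepted center
  for (l in locs) {
    d_own <- great_circle_m(lat[match(l$member_ids, ids)],
                            lon[match(l$member_ids, ids)],
                            l$center[["lat"]], l$center[["lon"]])
    expect_true(all(d_own <= l$radius_m + 1e-9))
  }
})

test_that("accepted locales always satisfy the definition invariants", {
  # messy user: overlapping clusters, stragglers
  withr::with_seed(102, {
    a <- cluster_latlon(40, -74, 40, sd_m = 30)
    b <- cluster_latlon(40.0013, -74, 25, sd_m = 30)  # ~145 m away, may contend
    c <- cluster_latlon(40.02, -74, 12, sd_m = 10)
    s <- cluster_latlon(40.01, -74.01, 6, sd_m = 2000)
  })
  lat <- c(a$lat, b$lat, c$lat, s$lat)
  lon <- c(a$lon, b$lon, c$lon, s$lon)
  locs <- extract_locales(lat, lon)
  expect_gt(length(locs), 0)
  for (l in locs) {
    expect_lte(l$radius_m, 100)
    expect_gte(l$count, 10)
  }
  # pairwise non-intersection and disjoint membership
  if (length(locs) > 1) {
    for (i in seq_along(locs)) for (j in seq_along(locs)) {
      if (i < j) {
        d <- great_circle_m(locs[[i]]$center[["lat"]], locs[[i]]$center[["lon"]],
                            locs[[j]]$center[["lat"]], locs[[j]]$center[["lon"]])
        expect_gte(d, locs[[i]]$radius_m + locs[[j]]$radius_m)
        expect_length(intersect(locs[[i]]$member_ids, locs[[j]]$member_ids), 0)
      }
    }
  }
  # determinism: same input, same output
  expect_identical(locs, extract_locales(lat, lon))
})

test_that("locale probabilities are count/N with rank ties broken by first visit", {
  ll <- cluster_latlon(40, -74, 10, sd_m = 0)
  locs <- extract_locales(ll$lat, ll$lon)
  prof <- locale_probabilities(locs, 20)
  expect_equal(prof$probability, 0.5)
  expect_equal(unname(mode_location(prof)[["lat"]]), 40, tolerance = 1e-6)

  empty <- locale_probabilities(list(), 5)
  expect_length(empty$probability, 0)
  expect_null(mode_location(empty))
  expect_error(locale_probabilities(list(), 0), "positive")

  # synthetic profile arithmetic: counts {30,20,10} over N=100
  fake <- lapply(c(30, 20, 10), function(k) list(
    center = c(lat = 40, lon = -74), radius_m = 10, count = as.integer(k),
    member_ids = character(k), first_time_index = 31 - k, rank = 0L))
  p <- locale_probabilities(fake, 100)
  expect_equal(p$probability, c(0.3, 0.2, 0.1))
  expect_lte(sum(p$probability), 1)

  # tie on counts: earliest first message wins rank 1
  withr::with_seed(103, {
    a <- cluster_latlon(40, -74, 12, sd_m = 3)
    b <- cluster_latlon(40.01, -74, 12, sd_m = 3)
  })
  lat <- c(rbind(b$lat, a$lat))  # interleave so b comes first
  lon <- c(rbind(b$lon, a$lon))
  locs <- extract_locales(lat, lon)
  expect_equal(locs[[1]]$first_time_index, 1)
})

test_that("Zipf fit recovers exact and simulated rank laws", {
  r <- 1:20
  p <- r^(-1.3) / sum(r^(-1.3))
  expect_equal(suppressWarnings(fit_zipf(r, p)$slope), -1.3, tolerance = 1e-12)
  p1 <- r^(-1) / sum(r^(-1))
  expect_equal(suppressWarnings(fit_zipf(r, p1)$slope), -1, tolerance = 1e-12)
  expect_error(fit_zipf(1, 0.5), "distinct ranks")

  # noisy per-user profiles with a common locale count (so the noise-free
  # pooled slope is exactly the generating exponent): multinomial sampling
  # noise must not move the fit by more than a few hundredths
  withr::with_seed(104, {
    pts <- do.call(rbind, lapply(1:150, function(u) {
      K <- 10
      pr <- (1:K)^(-1.3)
      pr <- 0.8 * pr / sum(pr)
      counts <- as.vector(stats::rmultinom(1, 5000, c(pr, 1 - sum(pr))))[1:K]
      data.frame(rank = 1:K, p = counts / 5000)
    }))
  })
  fit <- fit_zipf(pts$rank, pts$p)
  expect_lt(abs(fit$slope - (-1.3)), 0.03)
})

test_that("diurnal profiles sum to one and concentrate mode tweets in the morning", {
  # constructed user: all mode-locale messages at local hour 9
  withr::with_seed(105, {
    home <- cluster_latlon(40, -74, 12, sd_m = 2)
    away <- cluster_latlon(40.05, -74, 12, sd_m = 2)
  })
  t_home <- as.POSIXct("2011-03-07 09:30:00", tz = "UTC") + (0:11) * 86400 # Mondays..
  t_away <- as.POSIXct("2011-03-07 18:30:00", tz = "UTC") + (0:11) * 86400
  cp <- corpus(tibble::tibble(
    user_id = "u", message_id = sprintf("m%02d", 1:24),
    time_utc = c(t_home, t_away) + 300 * 60,  # stored as UTC for offset -300
    utc_offset_min = -300L,
    lat = c(home$lat, away$lat), lon = c(home$lon, away$lon),
    text = ""))
  prof <- locale_profiles(cp)
  dp <- diurnal_profiles(cp, prof)
  expect_equal(sum(dp$p_mode), 1, tolerance = 1e-12)
  expect_equal(sum(dp$p_other), 1, tolerance = 1e-12)
  # all mode mass in hour-9 bins across the week
  expect_equal(sum(dp$p_mode[dp$week_hour %% 24 == 9]), 1, tolerance = 1e-12)
  expect_equal(sum(dp$p_other[dp$week_hour %% 24 == 18]), 1, tolerance = 1e-12)
})

test_that("synthetic diurnal cycle shows the morning mode-locale excess", {
  gen <- heavy_population()
  sub <- apply_activity_threshold(gen$corpus, 800)
  profs <- heavy_profiles()
  dp <- diurnal_profiles(sub, profs[intersect(names(profs), unique(sub$user_id))])
  expect_equal(sum(dp$p_mode), 1, tolerance = 1e-9)
  morning <- dp$week_hour %% 24 %in% c(8, 9)
  expect_gt(sum(dp$p_mode[morning]), sum(dp$p_other[morning]))
})
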