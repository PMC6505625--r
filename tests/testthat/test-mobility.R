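test_that("local projection matches great-circle geometry and inverts", {
  org <- c(40.0, -74.0)
  p <- project_local(org[1], org[2], org)
  expect_equal(c(p$x, p$y), c(0, 0))

  # a point 0.001 degrees north sits one meridian arc away
  p2 <- project_local(40.001, -74.0, org)
  expect_equal(p2$y, EARTH_RADIUS_M * 0.001 * pi / 180, tolerance = 1e-9)
  expect_equal(p2$x, 0, tolerance = 1e-6)

  withr::with_seed(5, {
    lat <- 40 + runif(200, -2, 2)
    lon <- -74 + runif(200, -2, 2)
  })
  pl <- project_local(lat, lon, org)
  # radial distances are exact great-circle distances
  ora <- geosphere::distHaversine(cbind(-74, 40), cbind(lon, lat), r = EARTH_RADIUS_M)
  expect_equal(sqrt(pl$x^2 + pl$y^2), ora, tolerance = 1e-9)
  # round trip
  back <- unproject_local(pl$x, pl$y, org)
  expect_equal(back$lat, lat, tolerance = 1e-9)
  expect_equal(back$lon, lon, tolerance = 1e-9)
  expect_error(project_local(-40, 106, org), "antipodal")
})

test_that("expected location is the planar center of mass", {
  expect_equal(unname(expected_location(40.5, -73.5)), c(40.5, -73.5))
  # two points: planar midpoint
  el <- expected_location(c(40, 40.2), c(-74, -74))
  expect_equal(el[["lat"]], 40.1, tolerance = 1e-6)
  # 100 random points in a ~10 km box vs brute-force planar mean
  withr::with_seed(8, {
    x <- runif(100, -5000, 5000)
    y <- runif(100, -5000, 5000)
  })
  ll <- unproject_local(x, y, c(40, -74))
  el2 <- expected_location(ll$lat, ll$lon)
  brute <- unproject_local(mean(x), mean(y), c(40, -74))
  d_err <- great_circle_m(el2[["lat"]], el2[["lon"]], brute$lat, brute$lon)
  expect_lt(d_err, 1)
})

test_that("gyradius is the RMS distance from the expected location", {
  expect_equal(gyradius(rep(40, 5), rep(-74, 5)), 0)
  # two points 200 m apart: both sit 100 m from the midpoint
  ll <- unproject_local(c(-100, 100), c(0, 0), c(40, -74))
  expect_equal(gyradius(ll$lat, ll$lon), 100, tolerance = 1e-6)

  withr::with_seed(13, {
    x <- rnorm(500, 0, 3000)
    y <- rnorm(500, 0, 3000)
  })
  ll <- unproject_local(x, y, c(40, -74))
  ts <- trajectory_summary(ll$lat, ll$lon)
  ora <- geosphere::distHaversine(
    cbind(ts$expected_location[["lon"]], ts$expected_location[["lat"]]),
    cbind(ll$lon, ll$lat), r = EARTH_RADIUS_M)
  expect_equal(ts$gyradius_m, sqrt(mean(ora^2)), tolerance = 1e-3)
  expect_equal(ts$gyradius_m, sqrt(mean(ts$distances_m^2)), tolerance = 1e-12)
})

test_that("gyradius is invariant under translation/rotation and scales linearly", {
  withr::with_seed(21, {
    x <- rnorm(80, 0, 2000)
    y <- rnorm(80, 0, 2000)
  })
  g0 <- local({
    ll <- unproject_local(x, y, c(40, -74))
    gyradius(ll$lat, ll$lon)
  })
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  g_rot <- local({
    ll <- unproject_local(xr, yr, c(41, -80))  # rotated and translated
    gyradius(ll$lat, ll$lon)
  })
  expect_equal(g_rot, g0, tolerance = 1e-6)
  g_scaled <- local({
    ll <- unproject_local(3 * x, 3 * y, c(40, -74))
    gyradius(ll$lat, ll$lon)
  })
  expect_equal(g_scaled, 3 * g0, tolerance = 1e-4)
})

test_that("gyradius CCDF is a proper non-increasing step curve", {
  expect_equal(gyradius_ccdf(5)$fraction_ge, 1)
  cc <- gyradius_ccdf(c(1, 2, 3))
  expect_equal(cc$fraction_ge[cc$value == 2], 2 / 3)
  withr::with_seed(3, v <- rlnorm(200, 8, 1))
  cc <- gyradius_ccdf(v)
  expect_true(all(diff(cc$fraction_ge) <= 0))
  expect_equal(cc$fraction_ge[1], 1)
  expect_equal(cc$fraction_ge[nrow(cc)], 1 / 200)
  # pointwise counting oracle
  at <- sample(cc$value, 20)
  expect_equal(cc$fraction_ge[match(at, cc$value)],
               vapply(at, function(t) mean(v >= t), numeric(1)))
})

test_that("Moran's I and Geary's C match direct double-sum evaluation", {
  # 4x4 checkerboard on a unit grid: strong negative autocorrelation
  g <- expand.grid(x = 1:4, y = 1:4)
  v <- (g$x + g$y) %% 2
  mi <- morans_i(v, g$x, g$y, k = 4)
  gc <- gearys_c(v, g$x, g$y, k = 4)
  expect_lt(mi$statistic, 0)
  expect_gt(gc$statistic, 1)

  # brute-force double sums with the same weights
  W <- geohedon:::knn_weights(g$x, g$y, 4)
  n <- length(v)
  z <- v - mean(v)
  num_i <- 0
  num_c <- 0
  for (i in 1:n) for (j in 1:n) {
    num_i <- num_i + W[i, j] * z[i] * z[j]
    num_c <- num_c + W[i, j] * (v[i] - v[j])^2
  }
  expect_equal(mi$statistic, (n / sum(W)) * num_i / sum(z^2), tolerance = 1e-12)
  expect_equal(gc$statistic, ((n - 1) / (2 * sum(W))) * num_c / sum(z^2),
               tolerance = 1e-12)

  # independent implementation cross-check
  expect_equal(mi$statistic,
               ape::Moran.I(as.numeric(v), W)$observed, tolerance = 1e-12)

  expect_error(morans_i(rep(1, 16), g$x, g$y), "constant")
  expect_error(gearys_c(rep(1, 16), g$x, g$y), "constant")
})

test_that("permutation nulls center on the analytic expectations", {
  withr::with_seed(99, {
    x <- runif(40)
    y <- runif(40)
    v <- rnorm(40)
    mi <- replicate(300, morans_i(sample(v), x, y)$statistic)
    gc <- replicate(300, gearys_c(sample(v), x, y)$statistic)
  })
  expect_lt(abs(mean(mi) - (-1 / 39)), 0.02)
  expect_lt(abs(mean(gc) - 1), 0.05)
})
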