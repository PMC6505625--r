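# Per-user mobility summaries: expected location (trajectory center of
# mass), radius of gyration, per-message distances; population CCDF and
# global/local spatial autocorrelation statistics.

#' Expected location of a trajectory
#'
#' The center of mass of a user's message positions: positions are projected
#' to a local planar frame about the coordinate-wise midrange, averaged, and
#' mapped back to latitude/longitude. Treating each message as a prediction
#' of the user's position, this is the least-squares location.
#'
#' @param lat,lon Message coordinates in decimal degrees (one user).
#' @return Named numeric `c(lat, lon)`.
#' @export
expected_location <- function(lat, lon) {
  abort_if(length(lat) == 0, "expected_location needs at least one message")
  origin <- c((min(lat) + max(lat)) / 2, (min(lon) + max(lon)) / 2)
  pl <- project_local(lat, lon, origin)
  ll <- unproject_local(mean(pl$x), mean(pl$y), origin)
  c(lat = ll$lat, lon = ll$lon)
}

#' Radius of gyration of a trajectory
#'
#' The root-mean-square great-circle distance of a user's message positions
#' from their expected location; equivalently the RMSE of predicting each
#' position by the trajectory's center of mass. Zero if and only if all
#' positions coincide.
#'
#' @inheritParams expected_location
#' @return Gyradius in meters.
#' @export
gyradius <- function(lat, lon) {
  abort_if(length(lat) == 0, "gyradius needs at least one message")
  trajectory_summary(lat, lon)$gyradius_m
}

#' Full per-trajectory summary
#'
#' @inheritParams expected_location
#' @return A list with `expected_location` (named `c(lat, lon)`),
#'   `gyradius_m`, `distances_m` (per-message great-circle distance from the
#'   expected location, in input order) and `n`.
#' @export
trajectory_summary <- function(lat, lon) {
  abort_if(length(lat) == 0, "trajectory_summary needs at least one message")
  ctr <- expected_location(lat, lon)
  d <- great_circle_m(lat, lon, ctr[["lat"]], ctr[["lon"]])
  list(expected_location = ctr,
       gyradius_m = sqrt(mean(d^2)),
       distances_m = d,
       n = length(lat))
}

#' Mobility table for a whole corpus
#'
#' Computes the per-user summaries for every user in a corpus.
#'
#' @param corpus A [corpus()].
#' @return A list with two tibbles: `users` (`user_id`, `n`, `lat`, `lon`,
#'   `gyradius_m`) and `messages` (`message_id`, `user_id`, `distance_m` --
#'   the message's distance from its author's expected location).
#' @export
mobility_table <- function(corpus) {
  per_user <- split_users(corpus)
  rows <- vector("list", length(per_user))
  msg <- vector("list", length(per_user))
  for (i in seq_along(per_user)) {
    u <- per_user[[i]]
    ts <- trajectory_summary(u$lat, u$lon)
    rows[[i]] <- tibble::tibble(
      user_id = u$user_id[1], n = ts$n,
      lat = ts$expected_location[["lat"]],
      lon = ts$expected_location[["lon"]],
      gyradius_m = ts$gyradius_m)
    msg[[i]] <- tibble::tibble(
      message_id = u$message_id, user_id = u$user_id,
      distance_m = ts$distances_m)
  }
  list(users = do.call(rbind, rows) %||% tibble::tibble(),
       messages = do.call(rbind, msg) %||% tibble::tibble())
}

#' Complementary cumulative distribution of gyradii
#'
#' Step curve giving, for each observed value, the fraction of values at or
#' above it; starts at 1 and ends at `1/n` at the maximum.
#'
#' @param values Numeric vector (e.g. per-user gyradii).
#' @return A tibble with columns `value` (sorted ascending, unique) and
#'   `fraction_ge`.
#' @export
gyradius_ccdf <- function(values) {
  abort_if(length(values) == 0, "gyradius_ccdf needs at least one value")
  v <- sort(unique(values))
  n <- length(values)
  frac <- vapply(v, function(t) sum(values >= t) / n, numeric(1))
  tibble::tibble(value = v, fraction_ge = frac)
}

# Row-standardized k-nearest-neighbour spatial weights from planar coords.
knn_weights <- function(x, y, k = 8) {
  n <- length(x)
  abort_if(n < 3, "spatial statistics need at least 3 units")
  k <- min(k, n - 1)
  dmat <- as.matrix(stats::dist(cbind(x, y)))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    W[i, nb] <- 1 / k
  }
  W
}

#' Moran's I global spatial autocorrelation
#'
#' Classical Moran's I with row-standardized k-nearest-neighbour weights.
#' Under no spatial autocorrelation its expectation is `-1/(n-1)`.
#'
#' @param values Per-unit scalars (e.g. per-user gyradius at mode location).
#' @param x,y Planar coordinates of the units, meters.
#' @param k Number of nearest neighbours for the weight scheme.
#' @return A list with `statistic`, `expectation` (`-1/(n-1)`) and `n`.
#' @export
morans_i <- function(values, x, y, k = 8) {
  n <- length(values)
  abort_if(n < 3, "morans_i needs at least 3 units")
  abort_if(stats::var(values) == 0,
           "morans_i is undefined for constant values (zero variance)")
  W <- knn_weights(x, y, k)
  z <- values - mean(values)
  s0 <- sum(W)
  I <- (n / s0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  list(statistic = I, expectation = -1 / (n - 1), n = n)
}

#' Geary's C spatial autocorrelation
#'
#' Classical Geary's C with the same weight scheme as [morans_i()]; null
#' expectation 1, values above 1 indicate negative autocorrelation.
#'
#' @inheritParams morans_i
#' @return A list with `statistic`, `expectation` (1) and `n`.
#' @export
gearys_c <- function(values, x, y, k = 8) {
  n <- length(values)
  abort_if(n < 3, "gearys_c needs at least 3 units")
  abort_if(stats::var(values) == 0,
           "gearys_c is undefined for constant values (zero variance)")
  W <- knn_weights(x, y, k)
  s0 <- sum(W)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    num <- num + sum(W[i, ] * (values[i] - values)^2)
  }
  C <- ((n - 1) / (2 * s0)) * num / sum(z^2)
  list(statistic = C, expectation = 1, n = n)
}
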