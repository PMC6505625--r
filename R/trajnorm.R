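# Trajectory normalization: rotate every user's trajectory into a common
# home--work reference frame using the inertia tensor, then rescale each
# axis to unit spread so trajectory shapes are comparable across users.

#' Inertia tensor of a planar point set
#'
#' Second-moment matrix of mean-centered coordinates, treating every point
#' as an equally weighted unit mass: `M = [[mean(x^2), mean(xy)],
#' [mean(xy), mean(y^2)]]` after centering. Symmetric positive
#' semidefinite; its leading eigenvector is the trajectory's principal axis.
#'
#' @param x,y Planar coordinates in meters (one user).
#' @return A 2x2 symmetric matrix.
#' @export
inertia_tensor <- function(x, y) {
  abort_if(length(x) < 2 || nrow(unique(cbind(x, y))) < 2,
           "inertia tensor needs at least 2 distinct points")
  xc <- x - mean(x)
  yc <- y - mean(y)
  matrix(c(mean(xc^2), mean(xc * yc),
           mean(xc * yc), mean(yc^2)), 2, 2)
}

#' Normalize one trajectory into the common reference frame
#'
#' Translates a user's planar trajectory to its center of mass, rotates it
#' so the principal axis (leading eigenvector of the inertia tensor) lies
#' along the x-axis, resolves the 180-degree ambiguity so that the user's
#' mode location falls on the east (`x >= 0`) side, and divides each axis by
#' its post-rotation standard deviation (population convention, matching
#' the equal-mass tensor). In the resulting frame every user has mean
#' `(0, 0)` and per-axis variance 1; the home side is east.
#'
#' @param x,y Planar coordinates in meters (one user), e.g. from
#'   [project_local()] about the user's expected location.
#' @param mode_xy Optional planar position `c(x, y)` of the user's mode
#'   location (rank-1 locale center) used to orient the axis; when `NULL`,
#'   the median of the along-axis coordinate is used as a fallback.
#' @return A list of class `gh_normtraj`: `x`, `y` (dimensionless
#'   normalized coordinates), `sigma_x`, `sigma_y` (meters),
#'   `principal_axis_bearing` (degrees clockwise from north of the axis
#'   direction mapped to +x), `orientation_flip` (whether the 180-degree
#'   flip was applied), `eigenvalues` (descending), and `mode_x` (the
#'   normalized along-axis coordinate of the orienting location, always
#'   `>= 0`). Returns `NULL` (with a
#'   message) for degenerate trajectories whose minor-axis spread is zero.
#' @export
normalize_trajectory <- function(x, y, mode_xy = NULL) {
  abort_if(length(x) < 2 || nrow(unique(cbind(x, y))) < 2,
           "normalize_trajectory needs at least 2 distinct points")
  mx <- mean(x)
  my <- mean(y)
  xc <- x - mx
  yc <- y - my
  M <- inertia_tensor(x, y)
  eg <- eigen(M, symmetric = TRUE)
  ev <- eg$values # descending
  v <- eg$vectors[, 1]
  if (abs(ev[1] - ev[2]) < 1e-8 * max(ev[1], 1e-300)) {
    # eigen-tie: every direction is principal, so keep the east-west axis
    v <- c(1, 0)
    message("normalize_trajectory: equal eigenvalues; keeping the east-west axis")
  }
  theta <- atan2(v[2], v[1])
  # rotate principal axis onto the x-axis
  rot <- function(px, py, a) {
    list(x = cos(a) * px + sin(a) * py,
         y = -sin(a) * px + cos(a) * py)
  }
  r <- rot(xc, yc, theta)
  flip <- FALSE
  ref <- if (!is.null(mode_xy)) {
    rot(mode_xy[1] - mx, mode_xy[2] - my, theta)$x
  } else {
    stats::median(r$x)
  }
  if (ref < 0) {
    flip <- TRUE
    r$x <- -r$x
    r$y <- -r$y
    theta <- theta + pi
  }
  n <- length(x)
  sx <- sqrt(mean(r$x^2) - mean(r$x)^2)
  sy <- sqrt(mean(r$y^2) - mean(r$y)^2)
  if (sx <= 0 || sy <= 1e-9 * sx) {  # collinear up to rotation round-off
    message("normalize_trajectory: degenerate (collinear) trajectory excluded")
    return(NULL)
  }
  # bearing of the direction mapped to +x, degrees clockwise from north
  bearing <- (90 - theta * 180 / pi) %% 360
  if (flip) ref <- -ref
  structure(list(
    x = (r$x - mean(r$x)) / sx,
    y = (r$y - mean(r$y)) / sy,
    sigma_x = sx, sigma_y = sy,
    principal_axis_bearing = bearing,
    orientation_flip = flip,
    eigenvalues = ev,
    mode_x = ref / sx  # normalized along-axis position of the mode location
  ), class = "gh_normtraj")
}

#' Normalize every eligible user in a corpus
#'
#' Projects each user's messages about their expected location, extracts the
#' user's mode location (rank-1 locale) to orient the frame, and normalizes.
#' Users with fewer than `min_locations` messages or degenerate (collinear)
#' trajectories are excluded and counted.
#'
#' @param corpus A [corpus()].
#' @param min_locations Minimum number of messages per user (the density
#'   map's population uses more than 50; pass `51` with `strict = FALSE`
#'   semantics handled by the caller via [apply_activity_threshold()]).
#' @param locale_radius_m,locale_min_count Locale parameters forwarded to
#'   [extract_locales()] for mode-location orientation.
#' @return A list with `trajectories` (named list of `gh_normtraj`),
#'   `points` (tibble `user_id`, `x`, `y` pooled over users) and
#'   `n_excluded`.
#' @export
normalize_corpus <- function(corpus, min_locations = 51,
                             locale_radius_m = 100, locale_min_count = 10) {
  per_user <- split_users(corpus)
  out <- list()
  pts <- list()
  n_excluded <- 0L
  for (u in per_user) {
    if (nrow(u) < min_locations) next
    ctr <- expected_location(u$lat, u$lon)
    pl <- project_local(u$lat, u$lon, ctr)
    mode_xy <- NULL
    locs <- extract_locales(u$lat, u$lon, u$message_id,
                            radius_max = locale_radius_m,
                            min_count = locale_min_count)
    if (length(locs) > 0) {
      mc <- locs[[1]]$center
      mpl <- project_local(mc[["lat"]], mc[["lon"]], ctr)
      mode_xy <- c(mpl$x, mpl$y)
    }
    nt <- suppressMessages(normalize_trajectory(pl$x, pl$y, mode_xy))
    if (is.null(nt)) {
      n_excluded <- n_excluded + 1L
      next
    }
    uid <- u$user_id[1]
    out[[uid]] <- nt
    pts[[uid]] <- tibble::tibble(user_id = uid, x = nt$x, y = nt$y)
  }
  list(trajectories = out,
       points = if (length(pts)) do.call(rbind, pts) else
         tibble::tibble(user_id = character(), x = numeric(), y = numeric()),
       n_excluded = n_excluded)
}

#' Pooled density map of normalized locations
#'
#' Histogram of pooled normalized coordinates on a regular grid; cell values
#' are probabilities summing to exactly 1 over the grid. Points outside the
#' extent are dropped and counted.
#'
#' @param x,y Pooled normalized coordinates.
#' @param xlim,ylim Grid extents in normalized units.
#' @param cell Cell side length in normalized units.
#' @return A list with `grid` (tibble `x`, `y` cell centers and `p`),
#'   `n_dropped` and `n_used`.
#' @export
density_map <- function(x, y, xlim = c(-6, 6), ylim = c(-4, 4), cell = 0.1) {
  abort_if(length(x) == 0, "density_map needs at least one point")
  keep <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
  n_dropped <- sum(!keep)
  abort_if(!any(keep), "density_map: no points inside the grid extent")
  xb <- seq(xlim[1], xlim[2], by = cell)
  yb <- seq(ylim[1], ylim[2], by = cell)
  xi <- pmin(findInterval(x[keep], xb, rightmost.closed = TRUE), length(xb) - 1)
  yi <- pmin(findInterval(y[keep], yb, rightmost.closed = TRUE), length(yb) - 1)
  tab <- table(factor(xi, levels = seq_len(length(xb) - 1)),
               factor(yi, levels = seq_len(length(yb) - 1)))
  counts <- as.vector(tab)
  grid <- expand.grid(x = xb[-length(xb)] + cell / 2,
                      y = yb[-length(yb)] + cell / 2)
  # table() varies x fastest in as.vector order
  grid$p <- counts / sum(counts)
  list(grid = tibble::as_tibble(grid),
       n_dropped = n_dropped, n_used = sum(keep))
}

#' Principal-axis corridor profile
#'
#' One-dimensional histogram of the normalized along-axis coordinate for
#' messages inside the corridor `|y| <= half_width`, normalized to total
#' mass 1.
#'
#' @param x,y Pooled normalized coordinates.
#' @param half_width Corridor half-width in units of `sigma_y` (default 1).
#' @param xlim,cell Histogram extent and bin width along x.
#' @return A tibble with `x` (bin centers) and `p` (bin probabilities).
#' @export
corridor_profile <- function(x, y, half_width = 1, xlim = c(-6, 6), cell = 0.1) {
  abort_if(half_width <= 0, "half_width must be positive")
  keep <- abs(y) <= half_width & x >= xlim[1] & x <= xlim[2]
  abort_if(!any(keep), "corridor_profile: no points inside the corridor")
  xb <- seq(xlim[1], xlim[2], by = cell)
  xi <- pmin(findInterval(x[keep], xb, rightmost.closed = TRUE), length(xb) - 1)
  counts <- tabulate(xi, nbins = length(xb) - 1)
  tibble::tibble(x = xb[-length(xb)] + cell / 2, p = counts / sum(counts))
}

#' Isotropy ratio by gyradius decile
#'
#' The isotropy ratio of a trajectory is `sqrt(minor/major)` of its inertia
#' tensor eigenvalues (equivalently the minor-to-major axis spread ratio):
#' 1 for circularly symmetric movement, 0 for collinear. Users are grouped
#' into equal-count bins by gyradius and the ratio averaged per group.
#'
#' @param trajectories Named list of `gh_normtraj` from [normalize_corpus()].
#' @param gyradii Named numeric vector of gyradii (meters), names matching
#'   `trajectories`.
#' @param k Number of equal-count groups (default 10, deciles).
#' @return A tibble with `group`, `gyradius_median_m`, `mean_ratio`,
#'   `se_ratio` and `n`.
#' @export
isotropy_by_gyradius <- function(trajectories, gyradii, k = 10) {
  ids <- intersect(names(trajectories), names(gyradii))
  abort_if(length(ids) < k, "need at least k users with both a trajectory and a gyradius")
  ratio <- vapply(trajectories[ids], function(t) {
    sqrt(max(t$eigenvalues[2], 0) / t$eigenvalues[1])
  }, numeric(1))
  g <- gyradii[ids]
  bins <- equal_count_bins(g, k)
  agg <- lapply(split(seq_along(ids), bins), function(idx) {
    tibble::tibble(
      gyradius_median_m = stats::median(g[idx]),
      mean_ratio = mean(ratio[idx]),
      se_ratio = stats::sd(ratio[idx]) / sqrt(length(idx)),
      n = length(idx))
  })
  out <- do.call(rbind, agg)
  out <- cbind(tibble::tibble(group = as.integer(names(agg))), out)
  tibble::as_tibble(out)
}
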