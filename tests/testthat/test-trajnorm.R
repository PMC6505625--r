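test_that("inertia tensor equals the direct second-moment sum", {
  # points on the x-axis: no y moment, no cross moment
  M <- inertia_tensor(c(-2, -1, 0, 1, 2), rep(0, 5))
  expect_equal(M[1, 2], 0)
  expect_equal(M[2, 2], 0)

  withr::with_seed(31, {
    x <- rnorm(60, 0, 100)
    y <- rnorm(60, 0, 40)
  })
  M <- inertia_tensor(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  brute <- matrix(c(sum(xc^2), sum(xc * yc), sum(xc * yc), sum(yc^2)), 2) / 60
  expect_equal(M, brute, tolerance = 1e-12)

  # isotropic cloud: eigenvalues agree within sampling error
  withr::with_seed(32, {
    xi <- rnorm(5000)
    yi <- rnorm(5000)
  })
  ev <- eigen(inertia_tensor(xi, yi))$values
  expect_lt(ev[1] / ev[2], 1.15)
  expect_error(inertia_tensor(1, 1), "distinct")
})

test_that("normalized trajectories have unit spread and mode side east", {
  withr::with_seed(41, {
    # two-cluster home/work user: heavier cluster is home
    home <- cbind(rnorm(70, 0, 50), rnorm(70, 0, 50))
    work <- cbind(rnorm(30, 3000, 50), rnorm(30, 500, 50))
  })
  pts <- rbind(home, work)
  nt <- normalize_trajectory(pts[, 1], pts[, 2], mode_xy = c(0, 0))
  expect_equal(mean(nt$x), 0, tolerance = 1e-9)
  expect_equal(mean(nt$y), 0, tolerance = 1e-9)
  expect_equal(mean(nt$x^2) - mean(nt$x)^2, 1, tolerance = 1e-9)
  expect_equal(mean(nt$y^2) - mean(nt$y)^2, 1, tolerance = 1e-9)
  expect_gte(nt$mode_x, 0)
  # home cluster (first 70 points) sits on the positive-x side
  expect_gt(mean(nt$x[1:70]), 0)
  expect_true(all(diff(nt$eigenvalues) <= 0))
})

test_that("normalization is invariant to global rotation and translation", {
  withr::with_seed(43, {
    x <- c(rnorm(50, 0, 30), rnorm(50, 2000, 60))
    y <- c(rnorm(50, 0, 40), rnorm(50, 300, 50))
  })
  nt0 <- normalize_trajectory(x, y, mode_xy = c(0, 0))
  th <- 1.1
  xr <- cos(th) * x - sin(th) * y + 5e4
  yr <- sin(th) * x + cos(th) * y - 2e4
  mode_r <- c(cos(th) * 0 - sin(th) * 0 + 5e4, sin(th) * 0 + cos(th) * 0 - 2e4)
  nt1 <- normalize_trajectory(xr, yr, mode_xy = mode_r)
  expect_equal(nt1$x, nt0$x, tolerance = 1e-8)
  expect_equal(nt1$y, nt0$y, tolerance = 1e-8)
  expect_equal(nt1$eigenvalues, nt0$eigenvalues, tolerance = 1e-8)
})

test_that("normalizing an already-normalized trajectory is the identity", {
  withr::with_seed(44, {
    x <- c(rnorm(60, 0, 30), rnorm(40, 2500, 60))
    y <- c(rnorm(60, 0, 40), rnorm(40, 200, 50))
  })
  nt <- normalize_trajectory(x, y, mode_xy = c(0, 0))
  mode2 <- c(nt$mode_x, 0)
  nt2 <- normalize_trajectory(nt$x, nt$y, mode_xy = mode2)
  expect_equal(nt2$sigma_x, 1, tolerance = 1e-9)
  expect_equal(nt2$sigma_y, 1, tolerance = 1e-9)
  expect_equal(abs(nt2$x), abs(nt$x), tolerance = 1e-6)
})

test_that("collinear trajectories are excluded with a message", {
  expect_message(
    out <- normalize_trajectory(c(0, 100, 200, 300), c(0, 0, 0, 0)),
    "degenerate")
  expect_null(out)
})

test_that("density map and corridor profile have unit mass", {
  withr::with_seed(51, {
    x <- rnorm(5000)
    y <- rnorm(5000)
  })
  dm <- density_map(x, y)
  expect_equal(sum(dm$grid$p), 1, tolerance = 1e-12)
  expect_true(all(dm$grid$p >= 0))
  expect_equal(dm$n_dropped + dm$n_used, 5000)

  # all points in one cell
  dm1 <- density_map(rep(0.05, 10), rep(0.05, 10))
  expect_equal(max(dm1$grid$p), 1)

  cor <- corridor_profile(x, y)
  expect_equal(sum(cor$p), 1, tolerance = 1e-12)
  # corridor restriction: only |y| <= 1 points counted
  expect_equal(sum(corridor_profile(x, y, half_width = 1)$p), 1)

  # single-cluster population: unimodal at 0
  expect_equal(cor$x[which.max(cor$p)], 0.05, tolerance = 0.2)
})

test_that("corridor profile of a commuting population is bimodal, heavier east", {
  cfg <- population_config(n_individuals = 120, excursion_init_p = 0,
                           bot_fraction = 0, checkin_fraction = 0,
                           msgs_median = 120, msgs_sdlog = 0.2)
  gen <- generate_population(cfg, seed = 61, include_text = FALSE)
  nc <- normalize_corpus(gen$corpus, min_locations = 51)
  expect_gt(length(nc$trajectories), 50)
  prof <- corridor_profile(nc$points$x, nc$points$y, half_width = 1,
                           xlim = c(-6, 6), cell = 0.25)
  east <- sum(prof$p[prof$x > 0.25])
  west <- sum(prof$p[prof$x < -0.25])
  expect_gt(east, west)
  # distinct mass concentrations on both sides of the origin (home and work)
  expect_gt(max(prof$p[prof$x > 0.25]), 0.02)
  expect_gt(max(prof$p[prof$x < -0.25]), 0.02)
})

test_that("isotropy ratio is 1 for circular users, 0 for collinear, decreasing for commuters", {
  withr::with_seed(71, {
    xi <- rnorm(4000)
    yi <- rnorm(4000)
  })
  nt <- normalize_trajectory(xi, yi, mode_xy = c(1, 0))
  expect_equal(sqrt(nt$eigenvalues[2] / nt$eigenvalues[1]), 1, tolerance = 0.05)

  M <- inertia_tensor(c(0, 1, 2, 3), c(0, 1, 2, 3))
  ev <- eigen(M)$values
  expect_equal(sqrt(max(ev[2], 0) / ev[1]), 0, tolerance = 1e-9)

  trajs <- list(a = nt, b = nt, c = nt, d = nt)
  gy <- c(a = 1, b = 2, c = 3, d = 4)
  tab <- isotropy_by_gyradius(trajs, gy, k = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n, c(2L, 2L))
})
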