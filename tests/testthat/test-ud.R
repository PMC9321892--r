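test_that("a stationary bird with tiny location error has ~zero motion
           variance", {
  trk <- toy_track((0:99) * 5, rep(0, 100), rep(0, 100), err = 0.01)
  p <- estimate_motion_variance(trk, delta_floor = 0.01)
  expect_lt(mean(p$sigma2), 0.01)
})

test_that("Brownian motion variance is recovered within 10%", {
  est <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300; dt <- 5
    trk <- toy_track((0:(n - 1)) * dt,
                     cumsum(rnorm(n, 0, sqrt(2 * dt))),
                     cumsum(rnorm(n, 0, sqrt(2 * dt))), err = 0.01)
    mean(estimate_motion_variance(trk, delta_floor = 0.01)$sigma2)
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.1)
})

test_that("a variance step change is localized within the window margin", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    dt <- 5
    x <- cumsum(c(rnorm(200, 0, sqrt(1 * dt)), rnorm(200, 0, sqrt(10 * dt))))
    y <- cumsum(c(rnorm(200, 0, sqrt(1 * dt)), rnorm(200, 0, sqrt(10 * dt))))
    trk <- toy_track((0:399) * dt, x, y, err = 0.01)
    p <- estimate_motion_variance(trk, window_size = 31, margin = 11,
                                  delta_floor = 0.01)
    crossing <- which(p$sigma2 > sqrt(1 * 10))[1]  # geometric midpoint
    abs(crossing - 200) <= 11
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("short tracks fall back to a constant variance with a warning", {
  trk <- toy_track((0:19) * 5, rnorm(20, 0, 3), rnorm(20, 0, 3), err = 1)
  expect_warning(p <- estimate_motion_variance(trk, window_size = 31),
                 "constant")
  expect_equal(length(unique(p$sigma2)), 1)
})

test_that("every UD is a normalized density and degenerate windows follow
           the one-fix / zero-fix rules", {
  g <- grid_spec(cell = 2, xlim = c(-40, 40), ylim = c(-40, 40))
  trk <- toy_track(c(0, 30, 60), c(0, 5, 10), c(0, 5, 0), err = 4)
  ud <- compute_ud(trk, g, sigma2 = 1, delta_floor = 4)
  expect_s3_class(ud, "pf_ud")
  expect_lt(abs(sum(ud$z) - 1), 1e-9)
  expect_true(all(ud$z >= 0))
  # one fix: the UD is the fix's error kernel
  ud1 <- compute_ud(toy_track(0, 8, -3, err = 6), g, delta_floor = 6)
  expect_lt(abs(sum(ud1$z) - 1), 1e-9)
  td <- tidy(ud1)
  peak <- td[which.max(td$mass), ]
  expect_lt(abs(peak$x - 8), 2)
  expect_lt(abs(peak$y + 3), 2)
  # zero available fixes: no UD
  none <- toy_track(c(0, 5), c(NA, NA), c(NA, NA), available = FALSE)
  expect_null(compute_ud(none, g))
})

test_that("two-fix bridge matches the dense-quadrature analytic integral", {
  g <- grid_spec(cell = 1, xlim = c(-30, 50), ylim = c(-30, 30))
  trk <- toy_track(c(0, 60), c(0, 20), c(0, 0), err = 0.001)
  ud <- compute_ud(trk, g, sigma2 = 2, delta_floor = 0.001, nquad = 50)
  oracle <- bridge_density_oracle(g, 0, 60, c(0, 0), c(20, 0), 2,
                                  0.001, 0.001)
  expect_lt(total_variation(ud$z, oracle), 0.01)
})

test_that("bridge UD agrees with Monte-Carlo sampling of bridge positions", {
  g <- grid_spec(cell = 2.5, xlim = c(-30, 50), ylim = c(-30, 40))
  trk <- toy_track(c(0, 60, 120), c(0, 20, 10), c(0, 0, 15), err = 2)
  ud <- compute_ud(trk, g, sigma2 = 2, delta_floor = 2, nquad = 50)
  set.seed(9)
  N <- 1e5
  seg <- sample(1:2, N, replace = TRUE)  # equal segment durations
  a <- runif(N)
  x0 <- c(0, 20); x1 <- c(20, 10); y0 <- c(0, 0); y1 <- c(0, 15)
  v <- 60 * a * (1 - a) * 2 + (1 - a)^2 * 4 + a^2 * 4
  xs <- rnorm(N, x0[seg] + a * (x1[seg] - x0[seg]), sqrt(v))
  ys <- rnorm(N, y0[seg] + a * (y1[seg] - y0[seg]), sqrt(v))
  ix <- floor((xs - g$x0) / g$cell) + 1
  iy <- floor((ys - g$y0) / g$cell) + 1
  ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
  h <- as.matrix(table(factor(ix[ok], levels = 1:g$nx),
                       factor(iy[ok], levels = 1:g$ny)))
  expect_lt(total_variation(ud$z, h / sum(h)), 0.02)
})

test_that("disc masses are stable under grid refinement", {
  trk <- toy_track((0:49) * 5,
                   30 + 5 * sin((0:49) / 5), 10 + 5 * cos((0:49) / 5),
                   err = 5)
  m <- vapply(c(2, 1), function(cell) {
    g <- grid_spec(cell = cell, xlim = c(-20, 80), ylim = c(-40, 60))
    ud_disc_mass <- getFromNamespace("ud_disc_mass", "pairforage")
    ud_disc_mass(compute_ud(trk, g, sigma2 = 1), 30, 10, 10)
  }, numeric(1))
  expect_lt(abs(m[2] - m[1]) / m[1], 0.02)
})

test_that("an 8-hour session splits into 8 hourly or 48 ten-minute windows
           and empty hours are dropped", {
  trk <- simulate_pair_tracks(sim_config("coordinated", seed = 12))$male
  fx <- toy_track(trk$t, trk$x, trk$y, err = 5,
                  available = trk$available & !is.na(trk$x))
  g <- grid_spec(cell = 8)
  wh <- split_windows(fx, "hourly", g, t_start = 0, t_end = 8 * 3600,
                      sigma2 = 5)
  expect_equal(nrow(wh), 8)
  expect_true(all(wh$kept))
  wt <- split_windows(fx, "ten_min", g, t_start = 0, t_end = 8 * 3600,
                      sigma2 = 5)
  expect_equal(nrow(wt), 48)
  expect_equal(wt$availability,
               track_availability(fx, "ten_min", 5, 0, 8 * 3600)$availability)
  # blank one hour: its window survives as a row but carries no UD
  fx2 <- fx
  fx2$available[fx2$t >= 3600 & fx2$t < 7200] <- FALSE
  wh2 <- split_windows(fx2, "hourly", g, t_start = 0, t_end = 8 * 3600,
                       sigma2 = 5)
  expect_false(wh2$kept[2])
  expect_null(wh2$ud[[2]])
  expect_equal(wh2$availability[2], 0)
})
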