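angle_series <- function(t, ang) tibble::tibble(t = t, angle = ang)

test_that("circular correlation is 1 for identical or rotated series and
           invariant to constant rotations", {
  t <- seq(0, 995 * 5, by = 5)
  set.seed(3)
  a <- runif(length(t), -pi, pi)
  expect_equal(circular_correlation(angle_series(t, a),
                                    angle_series(t, a))$r, 1,
               tolerance = 1e-12)
  rot <- (a + 40 * pi / 180 + pi) %% (2 * pi) - pi
  expect_equal(circular_correlation(angle_series(t, a),
                                    angle_series(t, rot))$r, 1,
               tolerance = 1e-9)
  # adding a constant to either series never changes r
  set.seed(4)
  b <- runif(length(t), -pi, pi)
  r0 <- circular_correlation(angle_series(t, a), angle_series(t, b))$r
  b2 <- (b + 1.1 + pi) %% (2 * pi) - pi
  a2 <- (a - 0.7 + pi) %% (2 * pi) - pi
  expect_equal(circular_correlation(angle_series(t, a2),
                                    angle_series(t, b2))$r, r0,
               tolerance = 1e-9)
})

test_that("independent uniform angles give near-zero correlation", {
  set.seed(11)
  t <- seq(0, 999 * 5, by = 5)
  a <- runif(1000, -pi, pi); b <- runif(1000, -pi, pi)
  res <- circular_correlation(angle_series(t, a), angle_series(t, b))
  expect_lt(abs(res$r), 0.07)
  expect_gt(res$p, 0.001)
})

test_that("thinning keeps one fix per minute and degenerate series flag", {
  t <- seq(0, 599 * 5, by = 5)
  set.seed(5)
  a <- runif(length(t), -pi, pi)
  res <- circular_correlation(angle_series(t, a), angle_series(t, a),
                              resample_interval = 60)
  expect_equal(res$n, 50)
  deg <- circular_correlation(angle_series(t, rep(1, length(t))),
                              angle_series(t, a))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$r))
  expect_error(circular_correlation(angle_series(1:5, runif(5)),
                                    angle_series(1:5, runif(5))), "10")
})

test_that("angles at the nest are excluded from the series", {
  trk <- toy_track(c(0, 5, 10), c(0, 10, 0), c(0, 0, 10))
  ang <- foraging_angles(trk)
  expect_equal(nrow(ang), 2)
  expect_equal(ang$angle, c(0, pi / 2))
})

test_that("pair distances follow Euclidean geometry", {
  a <- toy_track(c(0, 5, 10), c(0, 1, 2), c(0, 0, 0))
  expect_equal(pair_distances(a, a)$summary$mean, 0)
  b <- toy_track(c(0, 5, 10), c(3, 4, 5), c(4, 4, 4))
  expect_equal(pair_distances(a, b)$distances$distance, c(5, 5, 5))
  none <- pair_distances(a[0, ], b)
  expect_equal(none$summary$n, 0)
})

test_that("coordinated pairs forage closer than independent pairs", {
  closer <- vapply(1:6, function(s) {
    dc <- pair_distances(
      simulate_pair_tracks(sim_config("coordinated", seed = s))$male,
      simulate_pair_tracks(sim_config("coordinated", seed = s))$female
    )$summary$mean
    di <- pair_distances(
      simulate_pair_tracks(sim_config("independent", seed = s))$male,
      simulate_pair_tracks(sim_config("independent", seed = s))$female
    )$summary$mean
    dc < di
  }, logical(1))
  expect_gte(mean(closer), 0.9)
})

test_that("proximity events honour the inclusive 10-m threshold and the
           5-s credit", {
  a <- toy_track(c(0, 5, 10), c(20, 20, 20), c(0, 0, 0))
  b <- toy_track(c(0, 5, 10), c(29.9, 30.1, 25), c(0, 0, 0))
  prox <- proximity_analysis(a, b)
  expect_equal(sum(prox$events), 2)     # 9.9 m and 5 m count, 10.1 m does not
  expect_equal(sum(prox$proximity_s), 10)
  expect_equal(prox$events[prox$bin == 2], 2L)  # midpoints ~25, ~22.5
})

test_that("both parents at the nest all session credit bin 0 entirely", {
  t <- seq(0, 8 * 3600 - 5, by = 5)
  a <- toy_track(t, rep(0, length(t)), rep(0, length(t)))
  prox <- proximity_analysis(a, a)
  expect_equal(prox$proximity_s[prox$bin == 0], 28800)
  expect_equal(sum(prox$proximity_s[prox$bin != 0]), 0)
})

test_that("proximity seconds are conserved across bins", {
  trk <- simulate_pair_tracks(sim_config("coordinated", seed = 9,
                                         session_hours = 2))
  prox <- proximity_analysis(trk$male, trk$female, n_bins = 8)
  j <- dplyr::inner_join(
    dplyr::filter(trk$male, available & !is.na(x)),
    dplyr::filter(trk$female, available & !is.na(x)),
    by = "t", suffix = c("_m", "_f"))
  d <- sqrt((j$x_m - j$x_f)^2 + (j$y_m - j$y_f)^2)
  mid <- (sqrt(j$x_m^2 + j$y_m^2) + sqrt(j$x_f^2 + j$y_f^2)) / 2
  expect_equal(sum(prox$proximity_s),
               5 * sum(d <= 10 & mid < 80))
})

test_that("the proximity mixed model reports the bin effect", {
  set.seed(21)
  prox <- purrr::map_dfr(1:6, function(n) {
    trk <- simulate_pair_tracks(sim_config("coordinated", seed = 300 + n,
                                           session_hours = 2))
    proximity_analysis(trk$male, trk$female, nest = sprintf("n%d", n))
  })
  fit <- proximity_model(prox)
  expect_equal(as.integer(fit$ndf), 7L)
  expect_true(fit$p >= 0 && fit$p <= 1)
})

test_that("provisioning correlation recovers an injected negative slope", {
  gen <- function(seed, beta = -2) {
    set.seed(seed)
    purrr::map_dfr(1:8, function(n) {
      visits <- rpois(8, 25)
      tibble::tibble(nest = sprintf("n%02d", n), day = 1L,
                     male_window = 0:7, female_window = 0:7, lag = 0L,
                     male_ud_id = paste0(n, "_m", 0:7),
                     female_ud_id = paste0(n, "_f", 0:7),
                     emd = 80 + rnorm(1, 0, 5) + beta * visits +
                       rnorm(8, 0, 6),
                     weight = 1, visits_true = visits)
    })
  }
  hits <- vapply(1:10, function(s) {
    recs <- gen(s)
    visits <- purrr::map_dfr(unique(recs$nest), function(nid) {
      r <- recs[recs$nest == nid, ]
      tibble::tibble(nest = nid, sex = "male",
                     t_in = rep(r$male_window * 3600 + 10, r$visits_true) +
                       sequence(r$visits_true),
                     t_out = rep(r$male_window * 3600 + 12, r$visits_true) +
                       sequence(r$visits_true))
    })
    res <- provisioning_correlation(recs, visits)
    res$slope < 0 && res$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("constant visit counts make the provisioning slope undefined and
           shuffled pairings centre the slope at zero", {
  recs <- tibble::tibble(nest = "n01", day = 1L, male_window = 0:7,
                         female_window = 0:7, lag = 0L,
                         male_ud_id = paste0("m", 0:7),
                         female_ud_id = paste0("f", 0:7),
                         emd = 50 + rnorm(8, 0, 5), weight = 1)
  visits <- tibble::tibble(sex = "male",
                           t_in = rep(0:7 * 3600, each = 3) + 1:3 * 100,
                           t_out = rep(0:7 * 3600, each = 3) + 1:3 * 100 + 5)
  res <- provisioning_correlation(recs, visits)
  expect_true(res$degenerate)
  expect_true(is.na(res$slope))
  # permutation null
  set.seed(31)
  recs2 <- recs
  recs2$emd <- 50 - 1.5 * c(5, 2, 8, 1, 9, 4, 7, 3) + rnorm(8, 0, 2)
  vis_n <- c(5, 2, 8, 1, 9, 4, 7, 3)
  slopes <- replicate(200, {
    perm <- sample(vis_n)
    visits_p <- tibble::tibble(
      sex = "male",
      t_in = unlist(lapply(0:7, function(h) h * 3600 + seq_len(perm[h + 1]) * 10)),
      t_out = unlist(lapply(0:7, function(h) h * 3600 + seq_len(perm[h + 1]) * 10 + 4)))
    visits_p <- visits_p[order(visits_p$t_in), ]
    provisioning_correlation(recs2, visits_p)$slope
  })
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)) + 0.2)
})
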