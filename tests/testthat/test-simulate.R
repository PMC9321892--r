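test_that("fully coordinated parents share every bout's patch", {
  trk <- simulate_pair_tracks(sim_config("coordinated", coordination_rho = 1,
                                         seed = 5))
  expect_equal(trk$bouts$male_patch, trk$bouts$female_patch)
})

test_that("a leader's patch sequence is copied with the configured delay", {
  trk <- simulate_pair_tracks(sim_config("leader", leader_lag = 1, seed = 5))
  b <- trk$bouts
  n <- nrow(b)
  expect_equal(b$female_patch[2:n], b$male_patch[1:(n - 1)])
  trk2 <- simulate_pair_tracks(sim_config("leader", leader_lag = 2,
                                          leader_sex = "female", seed = 5))
  b2 <- trk2$bouts
  expect_equal(b2$male_patch[3:n], b2$female_patch[1:(n - 2)])
})

test_that("an 8-hour session at 5-s pulses yields 5760 fix slots", {
  trk <- simulate_pair_tracks(sim_config("independent", seed = 2))
  expect_equal(nrow(trk$male), 5760)
  expect_equal(nrow(trk$female), 5760)
  expect_equal(diff(trk$male$t), rep(5, 5759))
})

test_that("independent parents share a patch at about the 1/K chance rate", {
  frac <- vapply(1:50, function(s) {
    b <- simulate_pair_tracks(sim_config("independent", seed = s,
                                         session_hours = 4))$bouts
    mean(b$male_patch == b$female_patch)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 1 / 6), 0.03)
})

test_that("simulation output is byte-identical under the same seed", {
  cfg <- sim_config("coordinated", seed = 17)
  a <- simulate_pair_tracks(cfg)
  b <- simulate_pair_tracks(cfg)
  expect_identical(a$male, b$male)
  expect_identical(a$female, b$female)
  expect_identical(a$visits, b$visits)
  arr <- receiver_array()
  expect_identical(simulate_detections(a, arr, rssi_model(), seed = 17),
                   simulate_detections(b, arr, rssi_model(), seed = 17))
  c <- simulate_pair_tracks(sim_config("coordinated", seed = 18))
  expect_false(identical(a$male, c$male))
})

test_that("time inside the array matches the configured fraction", {
  ins <- vapply(1:4, function(s) {
    trk <- simulate_pair_tracks(sim_config("independent", seed = s))
    mean(c(trk$male$available, trk$female$available))
  }, numeric(1))
  expect_lt(abs(mean(ins) - 0.73), 0.05)
})

test_that("nest visits are consistent, non-overlapping and ~2 min apart", {
  ivs <- unlist(lapply(1:5, function(s) {
    cfg <- sim_config("coordinated", seed = s)
    v <- simulate_nest_visits(cfg, simulate_pair_tracks(cfg))
    expect_true(all(v$t_in < v$t_out))
    for (sx in unique(v$sex)) {
      vs <- v[v$sex == sx, ]
      expect_true(all(diff(vs$t_in) > 0))
      expect_true(all(vs$t_out[-nrow(vs)] <= vs$t_in[-1]))
    }
    diff(v$t_in[v$sex == "male"])
  }))
  expect_lt(abs(mean(ivs) - 120) / 120, 0.1)
})

test_that("a zero-length session produces no fixes and no visits", {
  cfg <- sim_config("coordinated", session_hours = 0, seed = 1)
  trk <- simulate_pair_tracks(cfg)
  expect_equal(nrow(trk$male), 0)
  expect_equal(nrow(simulate_nest_visits(cfg, trk)), 0)
})

test_that("detections follow the path-loss model exactly when noiseless", {
  arr <- receiver_array()
  m0 <- rssi_model(noise_sd = 0)
  trk <- toy_track(0, arr$x[1] - 0, arr$y[1] - 1)  # 1 m from receiver 1
  trk$sex <- "male"; trk$patch <- NA
  det <- simulate_detections(trk, arr, m0, seed = 1)
  r1 <- det$rssi[det$receiver_id == arr$id[1]]
  expect_equal(r1, m0$P0)  # at d0 the receiver logs exactly P0
})

test_that("an infinite detection threshold yields an empty log and outside
           pulses never log", {
  arr <- receiver_array()
  trk <- simulate_pair_tracks(sim_config("independent", seed = 4,
                                         session_hours = 1))
  det <- simulate_detections(trk, arr, rssi_model(detect_threshold = Inf),
                             seed = 4)
  expect_equal(nrow(det), 0)
  det2 <- simulate_detections(trk, arr, rssi_model(), seed = 4)
  out_t <- trk$male$t[!trk$male$available]
  expect_equal(nrow(dplyr::filter(det2, tag_id == "m1", t %in% out_t)), 0)
})

test_that("most in-array pulses reach at least three receivers", {
  trk <- simulate_pair_tracks(sim_config("independent", seed = 6,
                                         session_hours = 2))
  det <- simulate_detections(trk, receiver_array(), rssi_model(), seed = 6)
  dm <- det[det$tag_id == "m1", ]
  n_rx <- table(dm$t)
  expect_gte(sum(n_rx >= 3) / sum(trk$male$available), 0.95)
})

test_that("configuration validation rejects impossible setups", {
  expect_error(sim_config(n_patches = 0))
  expect_error(sim_config(coordination_rho = 1.5))
  expect_error(sim_config(pulse_interval = 0))
})
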