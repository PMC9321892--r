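#' Simulate a desk-scale lag study
#'
#' Generates one replicate dataset of the lag analysis under a coordination
#' scenario: `n_nests` pairs, one 8-hour session each, true simulated fixes
#' (the RSSI observation stage is bypassed), a constant maximum-likelihood
#' motion variance per track, and hourly bridge UDs compared at all signed
#' lags. This is the workhorse for scenario-recovery and calibration studies,
#' where many replicates are needed and the triangulation and
#' dynamic-variance stages — validated separately — would dominate the run
#' time.
#'
#' @param scenario Coordination scenario (see [sim_config()]).
#' @param seed Replicate seed; nest `k` uses `seed * 1000 + k`.
#' @param n_nests Pairs per replicate.
#' @param sim Named list of [sim_config()] overrides.
#' @param cell UD cell size in metres.
#' @param max_lag Maximum absolute lag (windows).
#' @param max_cells,drop_tol Passed to [emd()].
#' @param mode Window mode, `"hourly"` or `"ten_min"`.
#' @param delta_floor Location-error floor (m) attached to the true fixes.
#' @return A `pf_lag_table` covering all nests.
#' @export
simulate_lag_study <- function(scenario, seed = 1L, n_nests = 8,
                               sim = list(), cell = 8, max_lag = 7,
                               max_cells = 15, drop_tol = 3e-3,
                               mode = "hourly", delta_floor = 5) {
  tabs <- lapply(seq_len(n_nests), function(k) {
    cfg <- do.call(sim_config,
                   c(list(scenario = scenario, seed = seed * 1000 + k), sim))
    trk <- simulate_pair_tracks(cfg)
    g <- grid_spec(cell = cell)
    as_fix <- function(tr) {
      tibble::tibble(t = tr$t, x = tr$x, y = tr$y, err = delta_floor,
                     available = tr$available & !is.na(tr$x))
    }
    session <- cfg$session_hours * 3600
    tm <- suppressWarnings(estimate_motion_variance(as_fix(trk$male),
                                                    dynamic = FALSE))
    tf <- suppressWarnings(estimate_motion_variance(as_fix(trk$female),
                                                    dynamic = FALSE))
    wm <- split_windows(tm, mode, g, t_start = 0, t_end = session,
                        delta_floor = delta_floor)
    wf <- split_windows(tf, mode, g, t_start = 0, t_end = session,
                        delta_floor = delta_floor)
    build_lag_table(wm, wf, max_lag = max_lag,
                    nest = sprintf("nest%02d", k),
                    max_cells = max_cells, drop_tol = drop_tol)
  })
  bind_lag_tables(tabs)
}
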