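#' Simulation configuration for a provisioning pair
#'
#' Bundles every parameter of the central-place-foraging pair simulator. The
#' defaults reproduce the study conditions the package targets: an 8-hour
#' recording day, tag pulses every 5 s, provisioning visits roughly every
#' 2 minutes, about 73% of time spent inside the 75-m receiver array, and six
#' foraging patches 20-70 m from the nest.
#'
#' @param scenario Coordination scenario, one of `"coordinated"`, `"leader"`,
#'   `"cyclic"` or `"independent"`:
#'   * `coordinated`: both parents follow a shared patch sequence, each
#'     deviating independently with probability `1 - coordination_rho`.
#'   * `leader`: one parent (the `leader_sex`) chooses patches freely; the
#'     other repeats the leader's patch sequence `leader_lag` bouts later.
#'   * `cyclic`: both parents rotate deterministically through the patches,
#'     completing a full rotation every `cycle_period` seconds.
#'   * `independent`: each parent draws its own patch sequence.
#' @param n_patches Number of foraging patches (>= 1).
#' @param patch_centers Optional two-column matrix/data frame of patch centre
#'   coordinates (m). When `NULL`, centres are drawn uniformly in the 20-70 m
#'   annulus around the nest.
#' @param bout_duration Duration in seconds of one foraging bout (the period a
#'   parent keeps returning to the same patch between nest visits).
#' @param leader_lag Follower's delay, in bouts, behind the leader
#'   (`leader` scenario).
#' @param leader_sex Which parent leads (`"male"` or `"female"`).
#' @param cycle_period Full patch-rotation period in seconds (`cyclic`
#'   scenario).
#' @param coordination_rho Probability in `[0, 1]` that a parent uses the
#'   shared patch in a bout (`coordinated` scenario).
#' @param pulse_interval Tag pulse interval in seconds.
#' @param session_hours Recording session length in hours.
#' @param visit_interval_mean Mean interval between successive nest visits of
#'   one parent, in seconds.
#' @param visit_duration_mean Mean time spent inside the nest box per visit,
#'   in seconds.
#' @param outside_array_prob Target long-run fraction of time a parent spends
#'   beyond the array (undetectable), in `[0, 1]`.
#' @param excursion_mean Mean duration in seconds of one out-of-array
#'   excursion.
#' @param patch_radius Radius in metres of the disc a parent wanders within a
#'   patch.
#' @param step_sd Standard deviation in metres of the per-pulse random-walk
#'   step while foraging.
#' @param flight_speed Commuting flight speed, m/s.
#' @param seed Integer master seed; fixes all randomness of the simulation.
#'
#' @return An object of class `pf_sim_config` (a named list).
#' @export
sim_config <- function(scenario = c("coordinated", "leader", "cyclic",
                                    "independent"),
                       n_patches = 6,
                       patch_centers = NULL,
                       bout_duration = 1200,
                       leader_lag = 1,
                       leader_sex = c("male", "female"),
                       cycle_period = 10800,
                       coordination_rho = 1,
                       pulse_interval = 5,
                       session_hours = 8,
                       visit_interval_mean = 120,
                       visit_duration_mean = 8,
                       outside_array_prob = 0.27,
                       excursion_mean = 150,
                       patch_radius = 15,
                       step_sd = 2.5,
                       flight_speed = 10,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  leader_sex <- match.arg(leader_sex)
  stopifnot(
    n_patches >= 1,
    bout_duration > 0,
    leader_lag >= 0,
    cycle_period > 0,
    coordination_rho >= 0, coordination_rho <= 1,
    pulse_interval > 0,
    session_hours >= 0,
    visit_interval_mean > 0,
    outside_array_prob >= 0, outside_array_prob < 1,
    patch_radius > 0, step_sd >= 0, flight_speed > 0
  )
  if (!is.null(patch_centers)) {
    patch_centers <- as.matrix(patch_centers)
    stopifnot(ncol(patch_centers) == 2, nrow(patch_centers) == n_patches)
  }
  structure(
    list(scenario = scenario, n_patches = as.integer(n_patches),
         patch_centers = patch_centers, bout_duration = bout_duration,
         leader_lag = as.integer(leader_lag), leader_sex = leader_sex,
         cycle_period = cycle_period, coordination_rho = coordination_rho,
         pulse_interval = pulse_interval, session_hours = session_hours,
         visit_interval_mean = visit_interval_mean,
         visit_duration_mean = visit_duration_mean,
         outside_array_prob = outside_array_prob,
         excursion_mean = excursion_mean,
         patch_radius = patch_radius, step_sd = step_sd,
         flight_speed = flight_speed, seed = as.integer(seed)),
    class = "pf_sim_config"
  )
}

#' @export
print.pf_sim_config <- function(x, ...) {
  cat("<pf_sim_config> scenario:", x$scenario,
      "| patches:", x$n_patches,
      "| session:", x$session_hours, "h",
      "| seed:", x$seed, "\n")
  invisible(x)
}
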