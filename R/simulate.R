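#' Simulate the paired tracks of two provisioning parents
#'
#' Event-driven central-place-foraging simulator. Each parent alternates nest
#' visits with foraging trips to one of `n_patches` patch centres; the patch
#' in use changes between bouts according to the coordination `scenario` (see
#' [sim_config()]). Occasional excursions take the bird beyond the array,
#' where it is undetectable. Within a patch the bird performs a reflected
#' random walk inside a disc of `patch_radius` metres.
#'
#' Positions are sampled on the tag-pulse grid (every `pulse_interval`
#' seconds, `t = 0, 5, 10, ...`). All randomness derives from `config$seed`;
#' the same configuration always yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `pf_tracks` with elements
#'   * `male`, `female`: tibbles with columns `sex`, `t` (s), `x`, `y` (m),
#'     `available` (inside the array and detectable) and `patch`;
#'   * `bouts`: tibble of true per-bout patch indices for both parents;
#'   * `patch_centers`: tibble of patch centre coordinates;
#'   * `visits`: tibble of nest visits (`sex`, `t_in`, `t_out`, seconds);
#'   * `config`: the input configuration.
#' @export
#' @examples
#' trk <- simulate_pair_tracks(sim_config("coordinated", session_hours = 1))
#' nrow(trk$male) # 720 pulse slots
simulate_pair_tracks <- function(config) {
  stopifnot(inherits(config, "pf_sim_config"))
  if (config$n_patches < 1) stop("at least one patch is required")

  centers <- config$patch_centers
  if (is.null(centers)) {
    centers <- local_seed(substream(config$seed, "patches"), {
      r <- sqrt(runif(config$n_patches, 20^2, 70^2))
      th <- runif(config$n_patches, 0, 2 * pi)
      cbind(x = r * cos(th), y = r * sin(th))
    })
  }
  colnames(centers) <- c("x", "y")

  session <- config$session_hours * 3600
  n_bouts <- max(1L, ceiling(session / config$bout_duration))
  bouts <- local_seed(substream(config$seed, "tracks", 0L),
                      patch_sequences(config, n_bouts))

  male <- local_seed(substream(config$seed, "tracks", 1L),
                     simulate_one_track("male", bouts$male_patch, centers,
                                        config))
  female <- local_seed(substream(config$seed, "tracks", 2L),
                       simulate_one_track("female", bouts$female_patch,
                                          centers, config))

  structure(
    list(
      male = male$track, female = female$track,
      bouts = tibble::tibble(
        bout = seq_len(n_bouts),
        t_start = (seq_len(n_bouts) - 1) * config$bout_duration,
        male_patch = bouts$male_patch,
        female_patch = bouts$female_patch
      ),
      patch_centers = tibble::as_tibble(centers),
      visits = dplyr::bind_rows(male$visits, female$visits),
      config = config
    ),
    class = "pf_tracks"
  )
}

# True per-bout patch indices for both parents under the four scenarios.
patch_sequences <- function(config, n_bouts) {
  K <- config$n_patches
  walk <- function(n) {
    s <- integer(n)
    s[1] <- sample.int(K, 1)
    if (n > 1) for (b in 2:n) {
      s[b] <- if (K == 1) 1L else sample.int(K, 1, prob = (seq_len(K) != s[b - 1]))
    }
    s
  }
  switch(config$scenario,
    coordinated = {
      shared <- walk(n_bouts)
      deviate <- function(s) {
        dev <- runif(n_bouts) > config$coordination_rho
        s[dev] <- sample.int(K, sum(dev), replace = TRUE)
        s
      }
      list(male_patch = deviate(shared), female_patch = deviate(shared))
    },
    leader = {
      lead <- walk(n_bouts)
      lagk <- config$leader_lag
      foll <- lead[pmax(seq_len(n_bouts) - lagk, 1)]
      if (config$leader_sex == "male") {
        list(male_patch = lead, female_patch = foll)
      } else {
        list(male_patch = foll, female_patch = lead)
      }
    },
    cyclic = {
      t0 <- (seq_len(n_bouts) - 1) * config$bout_duration
      s <- (floor((t0 %% config$cycle_period) / config$cycle_period * K) %% K) + 1L
      list(male_patch = as.integer(s), female_patch = as.integer(s))
    },
    independent = list(male_patch = walk(n_bouts), female_patch = walk(n_bouts))
  )
}

# One parent's continuous event timeline plus its rasterization to pulse
# slots. Runs inside a seeded substream.
simulate_one_track <- function(sex, patch_seq, centers, config) {
  session <- config$session_hours * 3600
  pulse <- config$pulse_interval
  n_slots <- floor(session / pulse)
  slot_t <- (seq_len(n_slots) - 1) * pulse

  # per-trip excursion probability giving the target outside-array time share
  f <- config$outside_array_prob
  q <- if (f <= 0) 0 else {
    min(0.95, f * config$visit_interval_mean / config$excursion_mean)
  }
  base_forage <- (config$visit_interval_mean - config$visit_duration_mean -
                    q * config$excursion_mean) / max(1 - q, 1e-9)

  # build events: type (1 visit, 2 flight out, 3 forage, 4 flight back, 5 excursion)
  ev_type <- integer(0); ev_t0 <- ev_t1 <- numeric(0); ev_patch <- integer(0)
  visits_in <- visits_out <- numeric(0)
  t <- 0
  push <- function(type, dur, patch = NA_integer_) {
    ev_type[[length(ev_type) + 1]] <<- type
    ev_t0[[length(ev_t0) + 1]] <<- t
    ev_t1[[length(ev_t1) + 1]] <<- t + dur
    ev_patch[[length(ev_patch) + 1]] <<- patch
    t <<- t + dur
  }
  while (t < session) {
    vd <- max(2, rgamma(1, shape = 4, rate = 4 / config$visit_duration_mean))
    visits_in <- c(visits_in, t); visits_out <- c(visits_out, min(t + vd, session))
    push(1L, vd)
    if (t >= session) break
    if (runif(1) < q) {
      push(5L, max(10, rexp(1, 1 / config$excursion_mean)))
    } else {
      bout <- min(length(patch_seq), floor(t / config$bout_duration) + 1)
      p <- patch_seq[bout]
      d <- sqrt(sum(centers[p, ]^2))
      ft <- d / config$flight_speed
      push(2L, ft, p)
      push(3L, max(5, rexp(1, 1 / max(base_forage - 2 * ft, 5))), p)
      push(4L, ft, p)
    }
  }

  # rasterize: event index per slot
  idx <- findInterval(slot_t, ev_t0)
  idx[idx < 1] <- 1L
  type <- ev_type[idx]
  patch <- ev_patch[idx]

  x <- y <- numeric(n_slots)
  avail <- type != 5L
  steps <- matrix(rnorm(2 * n_slots, 0, config$step_sd), ncol = 2)
  jit <- matrix(rnorm(2 * n_slots, 0, 0.5), ncol = 2)
  R <- config$patch_radius
  px <- py <- 0  # current within-patch walker position
  cur_ev <- -1L
  for (s in seq_len(n_slots)) {
    tp <- type[s]
    if (tp == 1L) {                      # at nest
      x[s] <- jit[s, 1]; y[s] <- jit[s, 2]
    } else if (tp == 5L) {               # outside the array
      x[s] <- NA_real_; y[s] <- NA_real_
    } else {
      cx <- centers[patch[s], 1]; cy <- centers[patch[s], 2]
      if (tp == 2L || tp == 4L) {        # commuting flight
        ev <- idx[s]
        frac <- (slot_t[s] - ev_t0[ev]) / max(ev_t1[ev] - ev_t0[ev], 1e-9)
        if (tp == 4L) frac <- 1 - frac
        x[s] <- frac * cx; y[s] <- frac * cy
      } else {                           # foraging random walk in the patch disc
        if (idx[s] != cur_ev) { px <- 0; py <- 0; cur_ev <- idx[s] }
        px <- px + steps[s, 1]; py <- py + steps[s, 2]
        r2 <- px * px + py * py
        if (r2 > R * R) {                # reflect back into the disc
          r <- sqrt(r2); fac <- (2 * R - r) / r
          if (fac < 0) fac <- 0.5 * R / r
          px <- px * fac; py <- py * fac
        }
        x[s] <- cx + px; y[s] <- cy + py
      }
    }
  }

  visits <- tibble::tibble(
    sex = sex,
    t_in = round(visits_in),
    t_out = pmax(round(visits_out), round(visits_in) + 1)
  )
  list(
    track = tibble::tibble(
      sex = sex, t = slot_t, x = x, y = y,
      available = avail, patch = ifelse(type == 3L, patch, NA_integer_)
    ),
    visits = visits
  )
}

#' Simulate receiver detection logs from tracks
#'
#' For every tag pulse of every available fix, each receiver logs
#' `RSSI = P0 - 10 * gamma * log10(d / d0) + N(0, noise_sd)` and retains the
#' pulse iff the noisy RSSI reaches the detection threshold. Pulses emitted
#' while a bird is outside the array produce no detections.
#'
#' @param tracks A `pf_tracks` object from [simulate_pair_tracks()], or a
#'   single track tibble.
#' @param array Receiver tibble from [receiver_array()].
#' @param model An [rssi_model()].
#' @param seed Integer seed for the detection noise.
#' @return Tibble with columns `tag_id`, `t` (s), `receiver_id`,
#'   `rssi` (dBm), sorted by time then tag then receiver.
#' @export
simulate_detections <- function(tracks, array, model = rssi_model(),
                                seed = 1L) {
  trk <- if (inherits(tracks, "pf_tracks")) {
    dplyr::bind_rows(
      dplyr::mutate(tracks$male, tag_id = "m1"),
      dplyr::mutate(tracks$female, tag_id = "f1")
    )
  } else {
    dplyr::mutate(tracks, tag_id = ifelse(.data$sex == "male", "m1", "f1"))
  }
  trk <- dplyr::filter(trk, .data$available & !is.na(.data$x))
  if (nrow(trk) == 0) {
    return(tibble::tibble(tag_id = character(), t = numeric(),
                          receiver_id = character(), rssi = numeric()))
  }
  nr <- nrow(array)
  local_seed(substream(seed, "detections"), {
    # distance matrix fixes x receivers
    dx <- outer(trk$x, array$x, "-")
    dy <- outer(trk$y, array$y, "-")
    d <- pmax(sqrt(dx^2 + dy^2), model$d0)
    rssi <- model$P0 - 10 * model$gamma * log10(d / model$d0)
    if (model$noise_sd > 0) {
      rssi <- rssi + matrix(rnorm(length(rssi), 0, model$noise_sd), nrow(rssi))
    }
    keep <- which(rssi >= model$detect_threshold, arr.ind = TRUE)
    out <- tibble::tibble(
      tag_id = trk$tag_id[keep[, 1]],
      t = trk$t[keep[, 1]],
      receiver_id = array$id[keep[, 2]],
      rssi = round(rssi[keep], 2)
    )
    dplyr::arrange(out, .data$t, .data$tag_id, .data$receiver_id)
  })
}

#' Nest-visit records of a simulated pair
#'
#' Returns the nest visits implied by the simulated tracks: one row per entry
#' of a parent into the nest box, with entry and exit times in seconds on the
#' shared clock. Visits are generated by the same event timeline as the
#' tracks, so they are exactly consistent with the parents' nest returns.
#'
#' @param config The [sim_config()] used for the simulation.
#' @param tracks A `pf_tracks` object from [simulate_pair_tracks()].
#' @return Tibble with columns `sex`, `t_in`, `t_out` (seconds).
#' @export
simulate_nest_visits <- function(config, tracks) {
  stopifnot(inherits(tracks, "pf_tracks"))
  tracks$visits
}
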