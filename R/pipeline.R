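#' Configuration of a full pipeline run
#'
#' Collects every knob of the end-to-end analysis: the simulation scenario
#' and its parameters, the RSSI model, the UD grid, dBBMM settings, lag
#' depths and output control. A run is reproducible from its configuration
#' alone; all randomness derives from `seed` via fixed named substreams.
#'
#' @param scenario Coordination scenario (see [sim_config()]).
#' @param n_nests Number of nests (pairs), each contributing one session.
#' @param seed Master seed.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param rssi An [rssi_model()].
#' @param grid A [grid_spec()].
#' @param use_triangulation Simulate RSSI detections and triangulate them
#'   (`TRUE`, the full observation model) or analyse the true simulated fixes
#'   directly (`FALSE`; location error is then the `delta_floor` only).
#' @param motion_model `"dynamic"` for the sliding-window motion-variance
#'   profile with change points, `"global"` for one constant maximum
#'   likelihood motion variance per track.
#' @param window_size,margin dBBMM sliding-window parameters (fixes).
#' @param delta_floor Lower bound (m) on per-fix location error SD.
#' @param max_lag_hourly,max_lag_fine Maximum absolute lag for the
#'   broad-scale (hourly) and fine-scale (10-min) tables.
#' @param min_availability Windows below this availability are dropped.
#' @param emd_max_cells Coarsening cap for [emd()].
#' @param out_dir Optional output directory for CSV tables and figures.
#' @param write_figures Write the correlogram figures when `out_dir` is set.
#' @return A list of class `pf_run_config`.
#' @export
run_config <- function(scenario = "coordinated", n_nests = 8, seed = 1L,
                       sim = list(), rssi = rssi_model(), grid = grid_spec(),
                       use_triangulation = TRUE,
                       motion_model = c("dynamic", "global"),
                       window_size = 31, margin = 11, delta_floor = 5,
                       max_lag_hourly = 7, max_lag_fine = 5,
                       min_availability = 0.1, emd_max_cells = 40,
                       out_dir = NULL, write_figures = TRUE) {
  motion_model <- match.arg(motion_model)
  structure(
    list(scenario = scenario, n_nests = as.integer(n_nests),
         seed = as.integer(seed), sim = sim, rssi = rssi, grid = grid,
         use_triangulation = use_triangulation, motion_model = motion_model,
         window_size = window_size, margin = margin,
         delta_floor = delta_floor, max_lag_hourly = max_lag_hourly,
         max_lag_fine = max_lag_fine, min_availability = min_availability,
         emd_max_cells = emd_max_cells, out_dir = out_dir,
         write_figures = write_figures),
    class = "pf_run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; `sim:` is a
#' nested block of [sim_config()] overrides; `rssi:` and `grid:` nested
#' blocks override [rssi_model()] and [grid_spec()] fields.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file.
#' @return A `pf_run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  args <- y
  if (!is.null(y$rssi)) args$rssi <- do.call(rssi_model, y$rssi)
  if (!is.null(y$grid)) args$grid <- do.call(grid_spec, y$grid)
  do.call(run_config, args)
}

#' Run the full coordination analysis pipeline
#'
#' Simulates (or ingests) each nest's session, triangulates the detection
#' logs into tracks, estimates hourly and 10-minute dynamic Brownian bridge
#' UDs, builds the signed-lag EMD tables at both scales, fits the weighted
#' mixed models with post-hoc lag contrasts, and runs the secondary analyses
#' (circular correlation of foraging angles, pair distances, proximity by
#' distance-from-nest bin, EMD versus provisioning rate). When
#' `config$out_dir` is set, all tables are written as CSV and the
#' correlograms as figures.
#'
#' @param config A [run_config()].
#' @param inputs Optional ingested field data from [ingest_real()] (single
#'   nest); when `NULL` the synthetic generator is used.
#' @return A list of class `pf_run` with elements `hourly` and `fine`
#'   (lag table, fit, posthoc), `behaviour` (angles, distances, proximity,
#'   provisioning), `covariates` fit, `nests` (per-nest artefacts) and
#'   `config`.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "pf_run_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, t_prev) {
    message(sprintf("[pairforage] %-14s %6.1f s (seed %d)", stage,
                    as.numeric(Sys.time() - t_prev, units = "secs"),
                    config$seed))
    Sys.time()
  }

  nests <- if (is.null(inputs)) {
    purrr::map(seq_len(config$n_nests), function(k) {
      analyse_nest(config, k, inputs = NULL)
    })
  } else {
    list(analyse_nest(config, 1L, inputs = inputs))
  }
  tl <- log_stage("nests", t0)

  hourly_tab <- bind_lag_tables(purrr::map(nests, "hourly_table"))
  fine_tab <- bind_lag_tables(purrr::map(nests, "fine_table"))

  fit_scale <- function(tab) {
    if (nrow(tab) == 0 || length(unique(tab$lag)) < 2) {
      return(list(table = tab, fit = NULL, posthoc = NULL))
    }
    fit <- fit_lag_model(tab)
    list(table = tab, fit = fit, posthoc = posthoc_lags(fit))
  }
  hourly <- fit_scale(hourly_tab)
  fine <- fit_scale(fine_tab)
  tl <- log_stage("lag models", tl)

  # covariate model on the hourly lag-0 records
  lag0 <- dplyr::filter(hourly_tab, .data$lag == 0)
  covs <- dplyr::bind_rows(purrr::map(nests, "covariates"))
  cov_fit <- NULL
  if (nrow(lag0) > 0 && length(unique(lag0$nest)) > 2) {
    lag0c <- dplyr::left_join(lag0, covs, by = "nest")
    lag0c$hour <- lag0c$male_window
    cov_fit <- tryCatch(fit_covariate_model(lag0c),
                        error = function(e) {
                          warning("covariate model failed: ",
                                  conditionMessage(e))
                          NULL
                        })
  }

  behaviour <- summarise_behaviour(nests, hourly_tab)
  tl <- log_stage("behaviour", tl)

  out <- structure(
    list(hourly = hourly, fine = fine, covariates = cov_fit,
         behaviour = behaviour, nests = nests, config = config),
    class = "pf_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(out, config)
  log_stage("total", t0)
  out
}

# simulate/ingest + triangulate + UDs + lag tables for one nest
analyse_nest <- function(config, k, inputs = NULL) {
  nest_id <- sprintf("nest%02d", k)
  nest_seed <- substream(config$seed, "nest", k)
  arr <- receiver_array()

  if (is.null(inputs)) {
    sim_args <- c(list(scenario = config$scenario, seed = nest_seed),
                  config$sim)
    scfg <- do.call(sim_config, sim_args)
    tracks <- simulate_pair_tracks(scfg)
    visits <- simulate_nest_visits(scfg, tracks)
    session <- scfg$session_hours * 3600
    pulse <- scfg$pulse_interval
    if (config$use_triangulation) {
      det <- simulate_detections(tracks, arr, config$rssi, seed = nest_seed)
      trk_m <- build_track(det[det$tag_id == "m1", ], arr, config$rssi,
                           pulse, 0, session)
      trk_f <- build_track(det[det$tag_id == "f1", ], arr, config$rssi,
                           pulse, 0, session)
    } else {
      det <- NULL
      as_fix <- function(tr, tag) {
        tibble::tibble(tag_id = tag, t = tr$t, x = tr$x, y = tr$y,
                       err = config$delta_floor,
                       n_rx = ifelse(tr$available, 3L, 0L),
                       available = tr$available & !is.na(tr$x))
      }
      trk_m <- as_fix(tracks$male, "m1")
      trk_f <- as_fix(tracks$female, "f1")
    }
  } else {
    det <- inputs$detections
    arr <- inputs$receivers
    visits <- inputs$visits
    pulse <- 5
    session <- ceiling(max(det$t) / 3600) * 3600
    trk_m <- build_track(det[grepl("^m", det$tag_id), ], arr, config$rssi,
                         pulse, 0, session)
    trk_f <- build_track(det[grepl("^f", det$tag_id), ], arr, config$rssi,
                         pulse, 0, session)
    tracks <- NULL
  }

  prof <- function(trk) {
    estimate_motion_variance(trk, config$window_size, config$margin,
                             config$delta_floor,
                             dynamic = config$motion_model == "dynamic")
  }
  trk_m <- suppressWarnings(prof(trk_m))
  trk_f <- suppressWarnings(prof(trk_f))

  wins <- function(trk, mode) {
    split_windows(trk, mode, grid = config$grid, pulse_interval = pulse,
                  t_start = 0, t_end = session,
                  min_availability = config$min_availability,
                  delta_floor = config$delta_floor)
  }
  m_h <- wins(trk_m, "hourly"); f_h <- wins(trk_f, "hourly")
  m_t <- wins(trk_m, "ten_min"); f_t <- wins(trk_f, "ten_min")

  hourly_table <- build_lag_table(m_h, f_h, config$max_lag_hourly,
                                  nest = nest_id,
                                  max_cells = config$emd_max_cells)
  fine_table <- build_lag_table(m_t, f_t, config$max_lag_fine,
                                nest = nest_id,
                                max_cells = config$emd_max_cells)

  covariates <- local_seed(substream(nest_seed, "visits", k), {
    tibble::tibble(nest = nest_id,
                   day = sample(10:25, 1),
                   n_chicks = sample(4:10, 1),
                   chick_age = sample(9:13, 1))
  })

  list(nest = nest_id, tracks = tracks, detections = det, visits = visits,
       track_m = trk_m, track_f = trk_f,
       hourly_windows = list(male = m_h, female = f_h),
       fine_windows = list(male = m_t, female = f_t),
       hourly_table = hourly_table, fine_table = fine_table,
       covariates = covariates)
}

summarise_behaviour <- function(nests, hourly_tab) {
  ang <- purrr::map_dfr(nests, function(nst) {
    am <- foraging_angles(nst$track_m); af <- foraging_angles(nst$track_f)
    res <- tryCatch(circular_correlation(am, af, resample_interval = 60),
                    error = function(e) NULL)
    if (is.null(res)) return(tibble::tibble())
    dplyr::mutate(res, nest = nst$nest, .before = 1)
  })
  dist <- purrr::map_dfr(nests, function(nst) {
    s <- pair_distances(nst$track_m, nst$track_f)$summary
    dplyr::mutate(s, nest = nst$nest, .before = 1)
  })
  prox <- purrr::map_dfr(nests, function(nst) {
    proximity_analysis(nst$track_m, nst$track_f, nest = nst$nest)
  })
  prox_fit <- if (length(unique(prox$nest)) > 1) proximity_model(prox) else NULL
  provis <- {
    lag0 <- dplyr::filter(hourly_tab, .data$lag == 0)
    visits <- purrr::map_dfr(nests, function(nst) {
      if (is.null(nst$visits) || nrow(nst$visits) == 0) return(tibble::tibble())
      dplyr::mutate(nst$visits, nest = nst$nest)
    })
    if (nrow(visits) == 0) {
      warning("no nest visits available; provisioning analysis skipped")
      NULL
    } else if (nrow(lag0) >= 3) {
      provisioning_correlation(lag0, visits)
    } else NULL
  }
  list(angles = ang, distances = dist, proximity = prox,
       proximity_fit = prox_fit, provisioning = provis)
}

write_run_outputs <- function(run, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0) {
      readr::write_csv(x, file.path(config$out_dir, paste0(name, ".csv")))
    }
  }
  wr(run$hourly$table, "emd_hourly")
  wr(run$fine$table, "emd_fine")
  wr(run$hourly$posthoc, "posthoc_hourly")
  wr(run$fine$posthoc, "posthoc_fine")
  wr(run$behaviour$proximity, "proximity_bins")
  wr(run$behaviour$distances, "pair_distances")
  wr(run$behaviour$angles, "circular_correlation")
  for (nst in run$nests) {
    if (!is.null(nst$detections)) {
      wr(dplyr::rename(nst$detections, timestamp_s = "t",
                       rssi_dbm = "rssi"),
         paste0("detections_", nst$nest))
    }
    if (!is.null(nst$visits)) {
      wr(dplyr::rename(nst$visits, t_in_s = "t_in", t_out_s = "t_out"),
         paste0("visits_", nst$nest))
    }
    fx <- dplyr::bind_rows(nst$track_m, nst$track_f)
    wr(dplyr::select(
         dplyr::rename(fx, t_s = "t", x_m = "x", y_m = "y", err_m = "err"),
         dplyr::any_of(c("tag_id", "t_s", "x_m", "y_m", "err_m", "n_rx",
                         "available"))),
       paste0("fixes_", nst$nest))
  }
  arr <- receiver_array()
  wr(dplyr::select(dplyr::rename(arr, x_m = "x", y_m = "y"),
                   "id", "x_m", "y_m"), "receivers")
  gl <- dplyr::bind_rows(
    if (!is.null(run$hourly$fit)) dplyr::mutate(glance(run$hourly$fit),
                                                scale = "hourly"),
    if (!is.null(run$fine$fit)) dplyr::mutate(glance(run$fine$fit),
                                              scale = "fine"))
  wr(gl, "lag_tests")
  if (isTRUE(config$write_figures)) {
    for (sc in c("hourly", "fine")) {
      tab <- run[[sc]]$table
      if (nrow(tab) > 0) {
        ggplot2::ggsave(file.path(config$out_dir,
                                  paste0("correlogram_", sc, ".pdf")),
                        ggplot2::autoplot(tab), width = 6, height = 4)
      }
    }
  }
  invisible(config$out_dir)
}

#' @export
print.pf_run <- function(x, ...) {
  cat("<pf_run>", x$config$scenario, "scenario,",
      length(x$nests), "nest(s)\n")
  if (!is.null(x$hourly$fit)) {
    cat("  broad scale: "); print(x$hourly$fit)
  }
  if (!is.null(x$fine$fit)) {
    cat("  fine scale:  "); print(x$fine$fit)
  }
  invisible(x)
}

#' Ingest field CSV logs into pipeline inputs
#'
#' Reads and validates detection, receiver and nest-visit CSV files in the
#' package's interchange schemas: detections `tag_id,timestamp_s,
#' receiver_id,rssi_dbm`; receivers `id,x_m,y_m`; visits `sex,t_in_s,
#' t_out_s`. Timestamps are seconds on a shared clock, coordinates metres
#' with the nest at the origin. Malformed rows are reported with their line
#' numbers; detections referencing unknown receivers, or with unsorted
#' timestamps, are rejected.
#'
#' @param detections_csv,receivers_csv,visits_csv File paths.
#' @return A list with `detections` (`tag_id`, `t`, `receiver_id`, `rssi`),
#'   `receivers` (`id`, `x`, `y`, `is_nest`) and `visits` (`sex`, `t_in`,
#'   `t_out`; `NULL` with a warning when the visits file is empty).
#' @export
ingest_real <- function(detections_csv, receivers_csv, visits_csv = NULL) {
  read_strict <- function(path, cols) {
    x <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    miss <- setdiff(cols, names(x))
    if (length(miss)) {
      stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "))
    }
    x
  }
  rec <- read_strict(receivers_csv, c("id", "x_m", "y_m"))
  receivers <- tibble::tibble(
    id = rec$id,
    x = as.numeric(rec$x_m), y = as.numeric(rec$y_m),
    is_nest = rec$id == "nest" | (as.numeric(rec$x_m) == 0 &
                                    as.numeric(rec$y_m) == 0)
  )
  bad <- which(!complete.cases(receivers[c("x", "y")]))
  if (length(bad)) {
    stop(basename(receivers_csv), ": malformed row(s) at line(s) ",
         paste(bad + 1, collapse = ", "))
  }

  det <- read_strict(detections_csv, c("tag_id", "timestamp_s",
                                       "receiver_id", "rssi_dbm"))
  detections <- tibble::tibble(
    tag_id = det$tag_id,
    t = as.numeric(det$timestamp_s),
    receiver_id = det$receiver_id,
    rssi = as.numeric(det$rssi_dbm)
  )
  bad <- which(!complete.cases(detections[c("t", "rssi")]))
  if (length(bad)) {
    stop(basename(detections_csv), ": malformed row(s) at line(s) ",
         paste(bad + 1, collapse = ", "))
  }
  if (is.unsorted(detections$t)) {
    stop(basename(detections_csv), ": timestamps are not sorted")
  }
  unknown <- setdiff(unique(detections$receiver_id), receivers$id)
  if (length(unknown)) {
    stop(basename(detections_csv), ": unknown receiver id(s): ",
         paste(unknown, collapse = ", "))
  }

  visits <- NULL
  if (!is.null(visits_csv)) {
    vis <- read_strict(visits_csv, c("sex", "t_in_s", "t_out_s"))
    if (nrow(vis) == 0) {
      warning(basename(visits_csv),
              ": no visits; provisioning analysis will be skipped")
    } else {
      visits <- tibble::tibble(sex = vis$sex,
                               t_in = as.numeric(vis$t_in_s),
                               t_out = as.numeric(vis$t_out_s))
      bad <- which(!complete.cases(visits[c("t_in", "t_out")]) |
                     visits$t_in >= visits$t_out)
      if (length(bad)) {
        stop(basename(visits_csv), ": malformed row(s) at line(s) ",
             paste(bad + 1, collapse = ", "))
      }
    }
  }
  list(detections = detections, receivers = receivers, visits = visits)
}
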