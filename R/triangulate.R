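#' Estimate one location from the detections of a single pulse
#'
#' Inverts the path-loss model to per-receiver distance estimates
#' `dhat_j = d0 * 10^((P0 - RSSI_j) / (10 * gamma))` and solves a weighted
#' nonlinear least-squares multilateration over the receiver positions
#' (weights proportional to `1 / dhat_j`, damped Gauss-Newton iteration
#' initialised at the signal-weighted receiver centroid). A fix needs at
#' least three non-collinear receivers; otherwise it is returned unavailable.
#' Solutions farther than `max_range` metres from the nest are flagged
#' unavailable (the array edge is soft, but far-out solutions are inversion
#' artefacts).
#'
#' @param detections Tibble of one pulse's detections: columns `receiver_id`,
#'   `rssi`.
#' @param array Receiver tibble from [receiver_array()].
#' @param model The [rssi_model()] used to invert distances.
#' @param max_range Clip radius in metres (default 100).
#' @return A one-row tibble: `x`, `y`, `err` (residual-based location error
#'   SD, m), `n_rx`, `available`.
#' @export
estimate_location <- function(detections, array, model = rssi_model(),
                              max_range = 100) {
  fx <- solve_fix(detections$receiver_id, detections$rssi, array, model,
                  max_range)
  tibble::tibble(x = fx[1], y = fx[2], err = fx[3],
                 n_rx = as.integer(fx[4]), available = fx[5] > 0)
}

# core solver; returns c(x, y, err, n_rx, available)
solve_fix <- function(receiver_id, rssi, array, model, max_range) {
  n <- length(receiver_id)
  bad <- c(NA_real_, NA_real_, NA_real_, n, 0)
  if (n < 3) return(bad)
  pos <- match(receiver_id, array$id)
  if (anyNA(pos)) {
    stop("unknown receiver id(s): ",
         paste(unique(receiver_id[is.na(pos)]), collapse = ", "))
  }
  rx <- array$x[pos]; ry <- array$y[pos]
  # collinearity check on receiver geometry
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sxx <- sum(cx * cx); syy <- sum(cy * cy); sxy <- sum(cx * cy)
  tr <- sxx + syy
  det2 <- sxx * syy - sxy * sxy
  disc <- sqrt(max(tr * tr / 4 - det2, 0))
  sv2 <- tr / 2 - disc                 # smallest eigenvalue of the 2x2 scatter
  if (sv2 < 1e-12 * max(tr, 1)) return(bad)

  dhat <- rssi_to_distance(model, rssi)
  w <- 1 / pmax(dhat, model$d0)
  x0 <- sum(w * rx) / sum(w); y0 <- sum(w * ry) / sum(w)
  fit <- trilaterate_cpp(rx, ry, dhat, w, x0, y0, 50L, 1e-6)
  if (sqrt(fit$x^2 + fit$y^2) > max_range) return(bad)
  err <- max(sqrt(fit$rss / sum(w) * n / max(n - 2, 1)), 0.1)
  c(fit$x, fit$y, err, n, 1)
}

#' Triangulate a detection log into a regular-slot track
#'
#' Groups detections into pulse slots (detections within half a pulse
#' interval of a nominal slot time are assigned to it), solves each slot with
#' [estimate_location()] and returns one fix row per slot of the session,
#' available or not.
#'
#' @param detections Detection tibble (`tag_id`, `t`, `receiver_id`, `rssi`)
#'   for a single tag, time-sorted.
#' @param array Receiver tibble.
#' @param model The [rssi_model()].
#' @param pulse_interval Pulse interval in seconds.
#' @param t_start,t_end Session bounds in seconds; default to the detection
#'   range rounded to whole slots.
#' @return Tibble with columns `tag_id`, `t`, `x`, `y`, `err`, `n_rx`,
#'   `available`, one row per slot.
#' @export
build_track <- function(detections, array, model = rssi_model(),
                        pulse_interval = 5, t_start = NULL, t_end = NULL) {
  if (nrow(detections) > 0 && is.unsorted(detections$t)) {
    stop("detections must be sorted by time")
  }
  tag <- if (nrow(detections)) detections$tag_id[1] else NA_character_
  if (is.null(t_start)) {
    t_start <- if (nrow(detections)) floor(min(detections$t) / pulse_interval) * pulse_interval else 0
  }
  if (is.null(t_end)) {
    t_end <- if (nrow(detections)) floor(max(detections$t) / pulse_interval) * pulse_interval + pulse_interval else 0
  }
  slots <- seq(t_start, t_end - pulse_interval, by = pulse_interval)
  if (length(slots) == 0 || nrow(detections) == 0) {
    return(tibble::tibble(tag_id = rep(tag, length(slots)), t = slots,
                          x = NA_real_, y = NA_real_, err = NA_real_,
                          n_rx = 0L, available = FALSE))
  }
  det <- detections
  det$slot <- round(det$t / pulse_interval) * pulse_interval
  det <- det[abs(det$t - det$slot) <= pulse_interval / 2 + 1e-9, ]
  rid <- split(det$receiver_id, det$slot)
  rs <- split(det$rssi, det$slot)
  sol <- matrix(NA_real_, length(rid), 5)
  for (i in seq_along(rid)) {
    sol[i, ] <- solve_fix(rid[[i]], rs[[i]], array, model, 100)
  }
  idx <- match(slots, as.numeric(names(rid)))
  out <- tibble::tibble(
    tag_id = tag, t = slots,
    x = sol[idx, 1], y = sol[idx, 2], err = sol[idx, 3],
    n_rx = ifelse(is.na(idx), 0L, as.integer(sol[idx, 4])),
    available = !is.na(idx) & sol[idx, 5] > 0
  )
  out$n_rx[is.na(out$n_rx)] <- 0L
  out
}

#' Per-window availability of triangulated locations
#'
#' Fraction of expected pulse slots in each window that yielded an available
#' fix: 720 slots per hour or 120 per 10-minute block at the default 5-s
#' pulse cadence. Availability is used downstream as the case weight of each
#' utilization distribution.
#'
#' @param track Fix tibble from [build_track()].
#' @param mode `"hourly"` or `"ten_min"` windows.
#' @param pulse_interval Pulse interval in seconds.
#' @param t_start,t_end Session bounds (s); default 0 to the last slot + 1.
#' @return Tibble with `window`, `t_start`, `t_end`, `n_available`,
#'   `n_expected`, `availability`.
#' @export
track_availability <- function(track, mode = c("hourly", "ten_min"),
                               pulse_interval = 5, t_start = 0,
                               t_end = NULL) {
  mode <- match.arg(mode)
  win <- if (mode == "hourly") 3600 else 600
  if (is.null(t_end)) {
    t_end <- if (nrow(track)) max(track$t) + pulse_interval else t_start
  }
  n_win <- max(0L, as.integer(ceiling((t_end - t_start) / win - 1e-9)))
  starts <- t_start + win * (seq_len(n_win) - 1)
  n_exp <- win / pulse_interval
  purrr::map_dfr(seq_along(starts), function(i) {
    s <- starts[i]
    in_win <- track$t >= s & track$t < s + win
    tibble::tibble(window = i - 1L, t_start = s, t_end = s + win,
                   n_available = sum(track$available[in_win]),
                   n_expected = n_exp,
                   availability = sum(track$available[in_win]) / n_exp)
  })
}
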