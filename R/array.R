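#' Build a receiver array around a nest
#'
#' Constructs the receiver geometry of an automated radio-tracking array:
#' concentric rings of receivers centred on the nest (at the origin), plus one
#' receiver at the nest itself. The default reproduces the field deployment
#' this package emulates: rings at 25, 50 and 75 m holding 7, 12 and 18
#' receivers (37 array receivers in total), spaced roughly 25 m from their
#' neighbours, with one extra receiver at the nest box.
#'
#' Receivers on each ring are equally spaced in angle with the first receiver
#' due north of the nest.
#'
#' @param ring_distances Numeric vector of ring radii in metres, sorted
#'   ascending. May be empty, in which case only the nest receiver is built.
#' @param ring_counts Integer vector, number of receivers per ring. Defaults
#'   to as many receivers as fit at `spacing_target` metres apart along each
#'   ring (7/12/18 for the default radii).
#' @param spacing_target Approximate distance in metres between neighbouring
#'   receivers on a ring, used when `ring_counts` is `NULL`.
#'
#' @return A tibble with one row per receiver and columns `id` (character),
#'   `x`, `y` (metres, nest at the origin) and `is_nest` (logical; exactly one
#'   `TRUE` row).
#' @export
#' @examples
#' arr <- receiver_array()
#' sum(!arr$is_nest) # 37 array receivers
receiver_array <- function(ring_distances = c(25, 50, 75),
                           ring_counts = NULL,
                           spacing_target = 25) {
  if (length(ring_distances) && any(ring_distances <= 0)) {
    stop("`ring_distances` must be positive")
  }
  if (is.unsorted(ring_distances)) {
    stop("`ring_distances` must be sorted ascending")
  }
  if (is.null(ring_counts)) {
    ring_counts <- if (identical(ring_distances, c(25, 50, 75))) {
      c(7L, 12L, 18L)      # the deployed 37-receiver configuration
    } else {
      vapply(ring_distances, function(r) {
        max(3L, as.integer(round(2 * pi * r / spacing_target)))
      }, integer(1))
    }
  }
  if (length(ring_counts) != length(ring_distances)) {
    stop("`ring_counts` must match `ring_distances` in length")
  }

  rings <- purrr::map2(ring_distances, ring_counts, function(r, n) {
    theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n  # first due north, clockwise
    tibble::tibble(x = r * cos(theta), y = r * sin(theta))
  })
  ring_tbl <- if (length(rings)) {
    arr <- dplyr::bind_rows(rings)
    tibble::tibble(
      id = sprintf("rx%02d", seq_len(nrow(arr))),
      x = round(arr$x, 6), y = round(arr$y, 6),
      is_nest = FALSE
    )
  } else {
    tibble::tibble(id = character(), x = numeric(), y = numeric(),
                   is_nest = logical())
  }
  out <- dplyr::bind_rows(
    ring_tbl,
    tibble::tibble(id = "nest", x = 0, y = 0, is_nest = TRUE)
  )
  stopifnot(!anyDuplicated(out$id))
  out
}

#' RSSI propagation model parameters
#'
#' Log-distance path-loss model for tag-to-receiver received signal strength:
#' `RSSI = P0 - 10 * gamma * log10(d / d0) + N(0, noise_sd)`, with detections
#' retained only when the (noisy) RSSI reaches `detect_threshold`. Distances
#' below `d0` are clamped to `d0`.
#'
#' @param P0 Reference received power (dBm) at distance `d0`.
#' @param d0 Reference distance in metres (> 0).
#' @param gamma Path-loss exponent (> 0); 2 is free space, larger values
#'   represent cluttered woodland.
#' @param noise_sd Standard deviation of Gaussian shadowing noise in dB
#'   (>= 0).
#' @param detect_threshold Receiver sensitivity in dBm; weaker pulses are not
#'   logged.
#' @return An object of class `pf_rssi_model` (a named list).
#' @export
rssi_model <- function(P0 = -40, d0 = 1, gamma = 2.5, noise_sd = 3,
                       detect_threshold = -85) {
  stopifnot(d0 > 0, gamma > 0, noise_sd >= 0)
  structure(
    list(P0 = P0, d0 = d0, gamma = gamma, noise_sd = noise_sd,
         detect_threshold = detect_threshold),
    class = "pf_rssi_model"
  )
}

#' Expected RSSI at a given distance
#'
#' @param model A [rssi_model()].
#' @param d Distance(s) in metres; clamped below at `d0`.
#' @return Expected RSSI in dBm (no noise).
#' @export
rssi_at <- function(model, d) {
  d <- pmax(d, model$d0)
  model$P0 - 10 * model$gamma * log10(d / model$d0)
}

#' Invert an RSSI value to a distance estimate
#'
#' @param model A [rssi_model()].
#' @param rssi Received signal strength(s) in dBm.
#' @return Estimated distance(s) in metres.
#' @export
rssi_to_distance <- function(model, rssi) {
  model$d0 * 10 ^ ((model$P0 - rssi) / (10 * model$gamma))
}
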