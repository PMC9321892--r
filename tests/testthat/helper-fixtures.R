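# Small constructors used across test files.

make_ud <- function(z, grid) {
  structure(list(z = z / sum(z), grid = grid, weight = 1), class = "pf_ud")
}

point_mass_ud <- function(grid, ix, iy) {
  z <- matrix(0, grid$nx, grid$ny)
  z[ix, iy] <- 1
  make_ud(z, grid)
}

random_ud <- function(grid, seed) {
  set.seed(seed)
  make_ud(matrix(runif(grid$nx * grid$ny), grid$nx, grid$ny), grid)
}

# a stationary-at-points truth track with constant error
toy_track <- function(t, x, y, err = 5, available = TRUE) {
  tibble::tibble(t = t, x = x, y = y, err = err,
                 available = rep_len(available, length(t)))
}

# noiseless detections of one pulse for a known position
pulse_detections <- function(p, array, model, receivers = NULL) {
  rows <- if (is.null(receivers)) seq_len(nrow(array)) else receivers
  d <- pmax(sqrt((array$x[rows] - p[1])^2 + (array$y[rows] - p[2])^2),
            model$d0)
  tibble::tibble(receiver_id = array$id[rows], rssi = rssi_at(model, d))
}
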