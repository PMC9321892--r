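#' Define a raster grid for utilization distributions
#'
#' @param cell Cell size in metres.
#' @param xlim,ylim Grid extent in metres (nest at the origin).
#' @return A list of class `pf_grid` with fields `x0`, `y0`, `cell`, `nx`,
#'   `ny`. Cell centres are at `x0 + (ix + 0.5) * cell`.
#' @export
grid_spec <- function(cell = 2, xlim = c(-100, 100), ylim = c(-100, 100)) {
  stopifnot(cell > 0, diff(xlim) > 0, diff(ylim) > 0)
  structure(
    list(x0 = xlim[1], y0 = ylim[1], cell = cell,
         nx = as.integer(round(diff(xlim) / cell)),
         ny = as.integer(round(diff(ylim) / cell))),
    class = "pf_grid"
  )
}

grid_centers <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell,
       y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell)
}

#' Estimate the dynamic motion-variance profile of a track
#'
#' Dynamic Brownian-bridge motion variance: within each sliding window of
#' `window_size` available fixes, every other fix is left out and predicted
#' from the bridge between its two neighbours; the Brownian motion variance
#' `sigma2` (m^2/s) maximizes the likelihood of the left-out fixes under
#' `N(mu(t), T * a * (1 - a) * sigma2 + (1 - a)^2 * delta_i^2 +
#' a^2 * delta_j^2)` per coordinate. One structural break per window is
#' allowed (at least `margin` fixes from either edge) and accepted when it
#' lowers the BIC; each fix's final value averages the fitted variances of
#' all windows covering it.
#'
#' @param track Fix tibble (columns `t`, `x`, `y`, `err`, `available`).
#' @param window_size Sliding window length in fixes (odd).
#' @param margin Minimum fixes between a break and the window edge (odd).
#' @param delta_floor Lower bound in metres for the per-fix location error SD.
#' @param dynamic When `FALSE`, skip the sliding windows and fit one constant
#'   maximum-likelihood motion variance for the whole track.
#' @return The input track with a `sigma2` column (m^2/s) appended;
#'   unavailable fixes carry the value interpolated from their neighbours.
#' @export
estimate_motion_variance <- function(track, window_size = 31, margin = 11,
                                     delta_floor = 5, dynamic = TRUE) {
  stopifnot(window_size >= 5, margin >= 1, margin <= window_size / 2)
  av <- which(track$available & !is.na(track$x))
  n <- length(av)
  tt <- track$t[av]; xx <- track$x[av]; yy <- track$y[av]
  dd <- pmax(if ("err" %in% names(track)) track$err[av] else 0, delta_floor)

  out <- track
  if (n < 5) {
    warning("track too short for motion-variance estimation; using fallback")
    out$sigma2 <- rep(1, nrow(track))
    return(out)
  }

  pred <- seq(2, n - 1, by = 2)
  Tt <- tt[pred + 1] - tt[pred - 1]
  a <- (tt[pred] - tt[pred - 1]) / Tt
  c1 <- Tt * a * (1 - a)
  c0 <- (1 - a)^2 * dd[pred - 1]^2 + a^2 * dd[pred + 1]^2
  mx <- xx[pred - 1] + a * (xx[pred + 1] - xx[pred - 1])
  my <- yy[pred - 1] + a * (yy[pred + 1] - yy[pred - 1])
  r2 <- (xx[pred] - mx)^2 + (yy[pred] - my)^2

  sg <- exp(seq(log(1e-4), log(1e4), length.out = 160))
  # log-likelihood of each predicted point at each candidate sigma2
  V <- outer(c1, sg) + c0                      # npred x G
  L <- -log(2 * pi * V) - r2 / (2 * V)
  CL <- apply(L, 2, cumsum)
  CL <- rbind(0, CL)                           # CL[k+1, ] = sum of first k rows

  refine <- function(lvec) {
    # parabolic refinement of the grid argmax in log-sigma2
    g <- which.max(lvec)
    if (g == 1 || g == length(sg)) return(list(s = sg[g], ll = lvec[g]))
    l0 <- lvec[g - 1]; l1 <- lvec[g]; l2 <- lvec[g + 1]
    den <- l0 - 2 * l1 + l2
    sh <- if (den < 0) 0.5 * (l0 - l2) / den else 0
    sh <- max(-0.5, min(0.5, sh))
    ls <- log(sg[g]) + sh * (log(sg[2]) - log(sg[1]))
    list(s = exp(ls), ll = l1)
  }

  if (!dynamic || n < window_size) {
    if (dynamic) {
      warning("fewer available fixes than `window_size`; constant-variance fit")
    }
    s2 <- refine(CL[length(pred) + 1, ] - CL[1, ])$s
    sig_av <- rep(s2, n)
  } else {
    W <- window_size
    acc <- numeric(n); cnt <- numeric(n)
    for (w in seq_len(n - W + 1)) {
      lo <- w + 1; hi <- w + W - 2
      k0 <- sum(pred < lo); k1 <- sum(pred <= hi)
      m <- k1 - k0
      if (m < 2) next
      ll_all <- CL[k1 + 1, ] - CL[k0 + 1, ]
      f0 <- refine(ll_all)
      bic0 <- -2 * f0$ll + log(m)
      # candidate breaks between predicted points, margin fixes from the edges
      cand <- seq_len(m - 1) + k0
      okl <- pred[cand] >= w + margin - 1
      okr <- pred[cand + 1] <= w + W - margin
      cand <- cand[okl & okr]
      best <- NULL
      for (j in cand) {
        fl <- refine(CL[j + 1, ] - CL[k0 + 1, ])
        fr <- refine(CL[k1 + 1, ] - CL[j + 1, ])
        ll <- fl$ll + fr$ll
        if (is.null(best) || ll > best$ll) {
          best <- list(ll = ll, j = j, sl = fl$s, sr = fr$s)
        }
      }
      if (!is.null(best) && (-2 * best$ll + 2 * log(m)) < bic0) {
        b <- pred[best$j]                      # break after this fix
        ixl <- w:b; ixr <- (b + 1):(w + W - 1)
        acc[ixl] <- acc[ixl] + best$sl; cnt[ixl] <- cnt[ixl] + 1
        acc[ixr] <- acc[ixr] + best$sr; cnt[ixr] <- cnt[ixr] + 1
      } else {
        ix <- w:(w + W - 1)
        acc[ix] <- acc[ix] + f0$s; cnt[ix] <- cnt[ix] + 1
      }
    }
    sig_av <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
    if (anyNA(sig_av)) {
      sig_av <- stats::approx(which(!is.na(sig_av)), sig_av[!is.na(sig_av)],
                              xout = seq_len(n), rule = 2)$y
    }
  }

  s_all <- rep(NA_real_, nrow(track))
  s_all[av] <- sig_av
  if (anyNA(s_all)) {
    s_all <- stats::approx(av, sig_av, xout = seq_len(nrow(track)),
                           rule = 2)$y
  }
  out$sigma2 <- s_all
  out
}

#' Compute the utilization distribution of a track window
#'
#' Dynamic Brownian bridge UD: the time-weighted average, over the bridge
#' segments between consecutive available fixes, of the bivariate normal
#' position density with mean `z_i + a * (z_{i+1} - z_i)` and isotropic
#' variance `T * a * (1 - a) * sigma2 + (1 - a)^2 * delta_i^2 +
#' a^2 * delta_{i+1}^2`, integrated over the within-segment time fraction
#' `a` with `nquad` midpoint quadrature points, discretized on `grid` and
#' normalized to unit mass. A single available fix yields the degenerate UD
#' `N(fix, delta^2)`; a window with no available fix yields `NULL`.
#'
#' @param track Fix tibble for one window (columns `t`, `x`, `y`, `err`,
#'   `available`, optionally `sigma2`).
#' @param grid A [grid_spec()].
#' @param sigma2 Motion variance in m^2/s: used when the track carries no
#'   `sigma2` column.
#' @param delta_floor Lower bound (m) on per-fix location error SD.
#' @param nquad Quadrature points per segment (>= 10 recommended).
#' @param weight Availability weight to attach to the UD.
#' @return An object of class `pf_ud`: list with the mass matrix `z`
#'   (`nx` x `ny`, sums to 1), the `grid`, and the `weight`; or `NULL` for an
#'   empty window.
#' @export
compute_ud <- function(track, grid = grid_spec(), sigma2 = 1,
                       delta_floor = 5, nquad = 10, weight = NULL) {
  av <- track$available & !is.na(track$x)
  tw <- track[av, ]
  if (nrow(tw) == 0) return(NULL)
  delta <- pmax(if ("err" %in% names(tw)) tw$err else 0, delta_floor)
  delta[is.na(delta)] <- delta_floor
  s2 <- if ("sigma2" %in% names(tw)) tw$sigma2 else rep(sigma2, nrow(tw))
  z <- bridge_ud_cpp(tw$t, tw$x, tw$y, delta, s2,
                     grid$x0, grid$y0, grid$cell, grid$nx, grid$ny,
                     as.integer(nquad))
  tot <- sum(z)
  if (tot <= 0) return(NULL)
  if (is.null(weight)) weight <- 1
  structure(list(z = z / tot, grid = grid, weight = weight),
            class = "pf_ud")
}

#' Split a session track into windowed utilization distributions
#'
#' Cuts the session (assumed to start on a window boundary at `t_start`) into
#' hourly or 10-minute windows, computes one UD per window and attaches each
#' window's availability (available fixes / expected pulse slots: 720 per
#' hour, 120 per 10 min at 5-s pulses) as its weight. Windows whose
#' availability falls below `min_availability` keep their row (weight
#' recorded) but carry no UD and are excluded from lag tables.
#'
#' @param track Fix tibble for a full session, ideally with a `sigma2` column
#'   from [estimate_motion_variance()].
#' @param mode `"hourly"` or `"ten_min"`.
#' @param grid A [grid_spec()].
#' @param pulse_interval Pulse interval (s).
#' @param t_start,t_end Session bounds (s).
#' @param min_availability Windows below this availability are dropped from
#'   analysis.
#' @param ... Passed to [compute_ud()].
#' @return Tibble with columns `window` (0-based index), `t_start`, `t_end`,
#'   `availability`, `kept`, and a list-column `ud` of `pf_ud` objects
#'   (`NULL` where dropped).
#' @export
split_windows <- function(track, mode = c("hourly", "ten_min"),
                          grid = grid_spec(), pulse_interval = 5,
                          t_start = 0, t_end = NULL,
                          min_availability = 0.1, ...) {
  mode <- match.arg(mode)
  avail <- track_availability(track, mode, pulse_interval, t_start, t_end)
  uds <- purrr::map(seq_len(nrow(avail)), function(i) {
    if (avail$availability[i] < min_availability) return(NULL)
    win <- track[track$t >= avail$t_start[i] & track$t < avail$t_end[i], ]
    compute_ud(win, grid = grid, weight = avail$availability[i], ...)
  })
  dplyr::mutate(avail,
                kept = avail$availability >= min_availability &
                  !purrr::map_lgl(uds, is.null),
                ud = uds)
}

#' @export
print.pf_ud <- function(x, ...) {
  g <- x$grid
  cat("<pf_ud>", g$nx, "x", g$ny, "cells of", g$cell,
      "m | weight", signif(x$weight, 3), "\n")
  invisible(x)
}

#' Tidy a utilization distribution into cell rows
#'
#' @param x A `pf_ud`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (cell centres, m) and `mass`.
#' @method tidy pf_ud
#' @export
tidy.pf_ud <- function(x, ...) {
  ctr <- grid_centers(x$grid)
  xs <- rep(ctr$x, times = x$grid$ny)
  ys <- rep(ctr$y, each = x$grid$nx)
  mass <- as.vector(x$z)
  tibble::tibble(x = xs, y = ys, mass = mass)
}

# total UD mass within `radius` metres of point (cx, cy); used for
# refinement checks
ud_disc_mass <- function(ud, cx, cy, radius) {
  ctr <- grid_centers(ud$grid)
  dx2 <- outer((ctr$x - cx)^2, (ctr$y - cy)^2, "+")
  sum(ud$z[dx2 <= radius^2])
}
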