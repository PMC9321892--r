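#' Foraging angles of a track relative to the nest
#'
#' Bearing `atan2(y, x)` of each available fix from the nest at the origin,
#' in radians in `[-pi, pi)`. Fixes exactly at the nest (radius below
#' `min_radius`) have no defined bearing and are excluded.
#'
#' @param track Fix tibble (`t`, `x`, `y`, `available`).
#' @param min_radius Fixes closer than this to the nest are dropped (m).
#' @return Tibble with `t` and `angle`.
#' @export
foraging_angles <- function(track, min_radius = 1e-9) {
  d <- track[track$available & !is.na(track$x), ]
  r <- sqrt(d$x^2 + d$y^2)
  d <- d[r >= min_radius, ]
  ang <- atan2(d$y, d$x)
  ang[ang >= pi] <- ang[ang >= pi] - 2 * pi
  tibble::tibble(t = d$t, angle = ang)
}

#' Circular correlation of the parents' foraging angles
#'
#' Jammalamadaka-SenGupta circular correlation coefficient between the
#' time-aligned bearings of the two parents:
#' `r = sum(sin(a - abar) * sin(b - bbar)) /
#'   sqrt(sum(sin^2(a - abar)) * sum(sin^2(b - bbar)))`
#' with `abar`, `bbar` the circular means, plus its asymptotic normal test.
#' `r` is invariant to adding any constant angle to either series. Because
#' consecutive 5-s fixes are strongly autocorrelated, the series can be
#' thinned to one fix per `resample_interval` seconds before testing.
#'
#' @param angles_m,angles_f Angle tibbles from [foraging_angles()] for the
#'   two parents (matched on `t`).
#' @param resample_interval Optional thinning interval in seconds (e.g. 60
#'   for one location per minute); `NULL` uses every shared fix.
#' @return A one-row tibble with `r`, `t_stat`, `p`, `n` and `degenerate`.
#' @export
circular_correlation <- function(angles_m, angles_f,
                                 resample_interval = NULL) {
  j <- dplyr::inner_join(angles_m, angles_f, by = "t",
                         suffix = c("_m", "_f"))
  if (!is.null(resample_interval)) {
    j <- j[j$t %% resample_interval == 0, ]
  }
  n <- nrow(j)
  if (n < 10) stop("need at least 10 aligned angle pairs")
  a <- j$angle_m; b <- j$angle_f
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - abar); sb <- sin(b - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) {
    return(tibble::tibble(r = NA_real_, t_stat = NA_real_, p = NA_real_,
                          n = n, degenerate = TRUE))
  }
  r <- sum(sa * sb) / den
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  t_stat <- sqrt(n * l20 * l02 / l22) * r
  p <- 2 * pnorm(-abs(t_stat))
  tibble::tibble(r = r, t_stat = t_stat, p = p, n = n, degenerate = FALSE)
}

#' Inter-parent distance series
#'
#' Euclidean distance between the two parents at every pulse slot where both
#' have an available fix.
#'
#' @param track_m,track_f Fix tibbles of the two parents.
#' @return A list with `distances` (tibble `t`, `distance`) and `summary`
#'   (one-row tibble: `n`, `mean`, `min`, `max`).
#' @export
pair_distances <- function(track_m, track_f) {
  j <- dplyr::inner_join(
    dplyr::filter(track_m, .data$available & !is.na(.data$x)),
    dplyr::filter(track_f, .data$available & !is.na(.data$x)),
    by = "t", suffix = c("_m", "_f"))
  d <- sqrt((j$x_m - j$x_f)^2 + (j$y_m - j$y_f)^2)
  list(
    distances = tibble::tibble(t = j$t, distance = d),
    summary = tibble::tibble(
      n = length(d),
      mean = if (length(d)) mean(d) else NA_real_,
      min = if (length(d)) min(d) else NA_real_,
      max = if (length(d)) max(d) else NA_real_)
  )
}

#' Proximity events binned by distance from the nest
#'
#' A proximity event is a pulse slot at which the parents are within
#' `threshold` metres of each other (inclusive). Each event contributes one
#' pulse interval (5 s by default) of cumulative proximity time to the 10-m
#' distance-from-nest bin indexed by the midpoint of the two parents'
#' distances from the nest (`bin = floor(mid / bin_width)`).
#'
#' @param track_m,track_f Fix tibbles of the two parents.
#' @param threshold Proximity threshold in metres (inclusive).
#' @param bin_width Bin width in metres.
#' @param n_bins Number of bins from the nest outwards (default 8 covers 0-80
#'   m; use 7 for binning strictly to the 75-m array edge, events beyond the
#'   last bin are dropped).
#' @param pulse_interval Seconds credited per event.
#' @param nest Identifier attached to the output rows.
#' @return Tibble with one row per bin: `nest`, `bin`, `bin_lo`, `bin_hi`,
#'   `events`, `proximity_s`.
#' @export
proximity_analysis <- function(track_m, track_f, threshold = 10,
                               bin_width = 10, n_bins = 8,
                               pulse_interval = 5, nest = "nest1") {
  j <- dplyr::inner_join(
    dplyr::filter(track_m, .data$available & !is.na(.data$x)),
    dplyr::filter(track_f, .data$available & !is.na(.data$x)),
    by = "t", suffix = c("_m", "_f"))
  d <- sqrt((j$x_m - j$x_f)^2 + (j$y_m - j$y_f)^2)
  rm_ <- sqrt(j$x_m^2 + j$y_m^2)
  rf_ <- sqrt(j$x_f^2 + j$y_f^2)
  mid <- (rm_ + rf_) / 2
  ev <- d <= threshold
  bin <- floor(mid / bin_width)
  keep <- ev & bin < n_bins
  counts <- table(factor(bin[keep], levels = 0:(n_bins - 1)))
  tibble::tibble(
    nest = nest,
    bin = 0:(n_bins - 1),
    bin_lo = bin_width * (0:(n_bins - 1)),
    bin_hi = bin_width * (1:n_bins),
    events = as.integer(counts),
    proximity_s = as.numeric(counts) * pulse_interval
  )
}

#' Mixed model of proximity time on distance-from-nest bin
#'
#' Fits `proximity_s ~ bin (categorical) + (1 | nest)` over the per-nest bin
#' tables and tests the bin effect with a Kenward-Roger F-test.
#'
#' @param prox Row-bound output of [proximity_analysis()] over several nests.
#' @return List with the `model` and `F`, `ndf`, `ddf`, `p` for the bin
#'   factor.
#' @export
proximity_model <- function(prox) {
  d <- as.data.frame(prox)
  stopifnot(length(unique(d$nest)) > 1)
  d$bin_f <- factor(d$bin)
  full <- lme4::lmer(proximity_s ~ bin_f + (1 | nest), data = d, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
  red <- lme4::lmer(proximity_s ~ 1 + (1 | nest), data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  kr <- suppressMessages(pbkrtest::KRmodcomp(full, red))
  st <- kr$test["Ftest", ]
  list(model = full, F = st$stat, ndf = st$ndf, ddf = st$ddf, p = st$p.value)
}

#' Relate hourly space-use similarity to provisioning rate
#'
#' Aggregates nest visits to hourly visit counts (both parents combined),
#' joins them to the hourly lag-0 EMD records, and fits the weighted mixed
#' model `emd ~ visits + (1 | nest)` (a plain weighted linear model when only
#' one nest is present). The slope's sign says whether hours of intense
#' provisioning coincide with more similar parental space use (negative
#' slope: higher provisioning, higher similarity).
#'
#' @param lag0_records Hourly lag-0 EMD records (`nest`, `male_window`,
#'   `emd`, `weight`); window indices are hours within the session.
#' @param visits Nest-visit tibble (`sex`, `t_in`, `t_out`), one nest per
#'   call, or with a `nest` column matching the records.
#' @return A one-row tibble with `slope`, `F`, `ndf`, `ddf`, `p`, `n_hours`
#'   and `degenerate` (TRUE when the visit counts are constant and the slope
#'   is undefined).
#' @export
provisioning_correlation <- function(lag0_records, visits) {
  d <- as.data.frame(lag0_records)
  d <- d[d$lag == 0 | is.null(d$lag), ]
  if (!"nest" %in% names(visits)) visits$nest <- d$nest[1]
  visits$hour <- floor(visits$t_in / 3600)
  vc <- dplyr::count(visits, .data$nest, .data$hour, name = "visits")
  d$hour <- d$male_window
  d <- dplyr::left_join(d, vc, by = c("nest", "hour"))
  d$visits[is.na(d$visits)] <- 0L
  if (nrow(d) < 3) stop("need at least 3 hourly records")
  if (length(unique(d$visits)) < 2) {
    return(tibble::tibble(slope = NA_real_, F = NA_real_, ndf = NA_real_,
                          ddf = NA_real_, p = NA_real_, n_hours = nrow(d),
                          degenerate = TRUE))
  }
  if (length(unique(d$nest)) > 1) {
    full <- lme4::lmer(emd ~ visits + (1 | nest), data = d,
                       weights = d$weight, REML = TRUE,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
    red <- lme4::lmer(emd ~ 1 + (1 | nest), data = d, weights = d$weight,
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    kr <- suppressMessages(pbkrtest::KRmodcomp(full, red))
    st <- kr$test["Ftest", ]
    tibble::tibble(slope = lme4::fixef(full)[["visits"]], F = st$stat,
                   ndf = st$ndf, ddf = st$ddf, p = st$p.value,
                   n_hours = nrow(d), degenerate = FALSE)
  } else {
    m <- stats::lm(emd ~ visits, data = d, weights = d$weight)
    an <- anova(m)
    tibble::tibble(slope = coef(m)[["visits"]], F = an["visits", "F value"],
                   ndf = an["visits", "Df"], ddf = an["Residuals", "Df"],
                   p = an["visits", "Pr(>F)"], n_hours = nrow(d),
                   degenerate = FALSE)
  }
}
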