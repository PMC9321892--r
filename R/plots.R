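#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Lag correlogram of an EMD table
#'
#' Mean earth mover's distance (with standard-error bars) per signed lag
#' class, the central figure of the analysis: spatio-temporal coordination
#' shows up as a dip at lag 0, a leading parent shifts the dip to the
#' leader's side, and periodic territory use produces repeated dips.
#'
#' @param object A `pf_lag_table`.
#' @param flip Reverse the y axis so that higher coordination (lower EMD)
#'   points upwards.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_lag_table
#' @export
autoplot.pf_lag_table <- function(object, flip = FALSE, ...) {
  s <- tidy(object)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$lag, y = .data$mean_emd)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_emd - .data$se,
                                        ymax = .data$mean_emd + .data$se),
                           width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "lag (windows; positive = female later)",
                  y = "EMD (m)") +
    ggplot2::theme_minimal()
  if (flip) p <- p + ggplot2::scale_y_reverse()
  p
}

#' Plot a utilization distribution
#'
#' @param object A `pf_ud`.
#' @param ... Unused.
#' @return A ggplot raster of the UD with the nest at the origin.
#' @method autoplot pf_ud
#' @export
autoplot.pf_ud <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "mass") +
    ggplot2::theme_minimal()
}

#' Summarise a lag table by lag class
#'
#' @param x A `pf_lag_table`.
#' @param ... Unused.
#' @return Tibble with `lag`, `n`, `mean_emd`, `se` (weighted means, using
#'   the record weights).
#' @method tidy pf_lag_table
#' @export
tidy.pf_lag_table <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$lag),
    n = dplyr::n(),
    mean_emd = sum(.data$emd * .data$weight) / sum(.data$weight),
    se = sd(.data$emd) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' Coefficients of a fitted lag model
#'
#' @param x A `pf_lag_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy pf_lag_fit
#' @export
tidy.pf_lag_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std.error = cf[, "Std. Error"])
}

#' One-row summary of the lag F-test
#'
#' @param x A `pf_lag_fit`.
#' @param ... Unused.
#' @return Tibble with `statistic` (F), `ndf`, `ddf`, `p.value`, `singular`,
#'   `nobs`.
#' @method glance pf_lag_fit
#' @export
glance.pf_lag_fit <- function(x, ...) {
  tibble::tibble(statistic = x$F, ndf = as.integer(x$ndf), ddf = x$ddf,
                 p.value = x$p, singular = x$singular,
                 nobs = nrow(x$records))
}

#' Term table of the covariate model
#'
#' @param x A `pf_cov_fit`.
#' @param ... Unused.
#' @return The per-variable F-test table accumulated during backward
#'   selection.
#' @method tidy pf_cov_fit
#' @export
tidy.pf_cov_fit <- function(x, ...) {
  tibble::as_tibble(x$term_table)
}
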