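#' Fit the mixed model for the lag effect on EMD
#'
#' Weighted linear mixed model of earth mover's distance on the signed lag
#' (treated as a categorical factor), with random intercepts for the male UD
#' identity and the female UD identity nested in nest (each UD appears in
#' many comparisons, so these absorb the pseudo-replication), plus a nest
#' intercept when several nests are present. Case weights are the products of
#' the two UDs' availability weights. The lag main effect is tested with an
#' F-test using the Kenward-Roger small-sample approximation; its numerator
#' degrees of freedom equal the number of lag classes minus one.
#'
#' @param records A `pf_lag_table` from [build_lag_table()] /
#'   [bind_lag_tables()].
#' @return An object of class `pf_lag_fit`: list with the `lme4` `model`, the
#'   F statistic `F`, `ndf`, `ddf`, `p` for the lag factor, `singular` flag
#'   and the input `records`.
#' @export
fit_lag_model <- function(records) {
  d <- as.data.frame(records)
  stopifnot(nrow(d) > 0, all(d$weight > 0), all(d$weight <= 1))
  d$lag_f <- factor(d$lag)
  if (nlevels(d$lag_f) < 2) stop("need at least 2 lag classes")
  multi_nest <- length(unique(d$nest)) > 1

  terms <- c(if (multi_nest) "(1 | nest)",
             "(1 | male_ud_id)", "(1 | female_ud_id)")
  fit <- fit_lmm_drop("emd ~ lag_f", terms, d)
  red <- fit_lmm_drop("emd ~ 1", fit$kept, d)
  kr <- suppressMessages(pbkrtest::KRmodcomp(fit$model, red$model))
  st <- kr$test["Ftest", ]

  structure(
    list(model = fit$model, F = st$stat, ndf = st$ndf, ddf = st$ddf,
         p = st$p.value, singular = lme4::isSingular(fit$model, tol = 1e-5),
         dropped_random = fit$dropped, records = tibble::as_tibble(d)),
    class = "pf_lag_fit"
  )
}

# fit a weighted LMM, dropping the smallest-variance random term on failure
fit_lmm_drop <- function(fixed, re_terms, d) {
  dropped <- character(0)
  repeat {
    form <- as.formula(paste(fixed, "+", paste(re_terms, collapse = " + ")))
    m <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = d, weights = d$weight, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
      )),
      error = function(e) e
    )
    if (!inherits(m, "error")) {
      return(list(model = m, kept = re_terms, dropped = dropped))
    }
    if (length(re_terms) <= 1) stop("mixed model could not be fitted: ",
                                    conditionMessage(m))
    dropped <- c(dropped, re_terms[length(re_terms)])
    re_terms <- re_terms[-length(re_terms)]
  }
}

#' @export
print.pf_lag_fit <- function(x, ...) {
  cat(sprintf("<pf_lag_fit> lag F(%d, %.1f) = %.3f, p = %.4g%s\n",
              as.integer(x$ndf), x$ddf, x$F, x$p,
              if (x$singular) " [boundary random-effect variance]" else ""))
  invisible(x)
}

#' Post-hoc pairwise comparison of lag classes
#'
#' All pairwise contrasts between lag classes on the fitted model, with
#' Tukey-style single-step multiplicity adjustment, summarized as compact
#' letter groups: classes sharing no letter differ significantly at `alpha`.
#'
#' @param fit A `pf_lag_fit`.
#' @param alpha Significance level for the letter display.
#' @param adjust Multiplicity adjustment passed to `emmeans` (default
#'   `"tukey"`).
#' @return Tibble with `lag`, `emmean`, `se` and `group` (letters).
#' @export
posthoc_lags <- function(fit, alpha = 0.05, adjust = "tukey") {
  emm <- emmeans::emmeans(fit$model, "lag_f", lmer.df = "satterthwaite")
  means <- as.data.frame(emm)
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = adjust))
  lev <- as.character(means$lag_f)
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  cmb <- utils::combn(k, 2)  # "pairwise" contrasts come in combn order
  stopifnot(ncol(cmb) == nrow(prs))
  for (i in seq_len(ncol(cmb))) {
    if (isTRUE(prs$p.value[i] < alpha)) {
      sig[cmb[1, i], cmb[2, i]] <- sig[cmb[2, i], cmb[1, i]] <- TRUE
    }
  }
  letters_v <- cld_letters(!sig, order(means$emmean))
  tibble::tibble(
    lag = as.integer(lev),
    emmean = means$emmean,
    se = means$SE,
    group = letters_v
  ) |> dplyr::arrange(.data$lag)
}

# Compact letter display from a logical "not significantly different"
# adjacency matrix: one letter per maximal clique, assigned in mean order.
cld_letters <- function(ns, ord) {
  k <- nrow(ns)
  diag(ns) <- FALSE
  cliques <- list()
  # Bron-Kerbosch with pivoting on the small class graph
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      cliques[[length(cliques) + 1]] <<- sort(R)
      return(invisible())
    }
    pivot <- c(P, X)[1]
    for (v in setdiff(P, which(ns[pivot, ]))) {
      nb <- which(ns[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  # order cliques by the rank of their best-ranked member
  rnk <- match(seq_len(k), ord)
  cliques <- cliques[order(vapply(cliques, function(cl) min(rnk[cl]), 0))]
  out <- rep("", k)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[(i - 1) %% 26 + 1])
  }
  out
}

#' Covariate model for lag-0 EMD with backward selection
#'
#' Fits a weighted mixed model of lag-0 EMD on nest/time covariates with a
#' nest random intercept, then removes the least significant covariate one at
#' a time (Kenward-Roger F-test per term) until only terms significant at
#' `alpha` remain. Covariates with pairwise R-squared at or above 0.9 abort
#' the fit with a collinearity diagnostic.
#'
#' @param records Tibble of hourly lag-0 EMD records carrying the covariate
#'   columns plus `nest`, `emd` and `weight`.
#' @param covariates Character vector of covariate column names.
#' @param alpha Retention threshold.
#' @return An object of class `pf_cov_fit`: list with the final `model`
#'   (`NULL` if no covariate survives), the per-variable `term_table` (F,
#'   ndf, ddf, p at the step the variable was dropped or in the final model),
#'   the `dropped` log, and `retained` names.
#' @export
fit_covariate_model <- function(records,
                                covariates = c("hour", "day", "n_chicks",
                                               "chick_age"),
                                alpha = 0.05) {
  d <- as.data.frame(records)
  stopifnot(all(covariates %in% names(d)), all(c("emd", "nest", "weight")
                                               %in% names(d)))
  keep <- covariates[vapply(covariates, function(v) {
    length(unique(d[[v]])) > 1
  }, logical(1))]
  if (length(keep) >= 2) {
    cc <- stats::cor(d[keep])^2
    diag(cc) <- 0
    if (any(cc >= 0.9)) {
      bad <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", keep[bad[1]], " and ", keep[bad[2]],
           " (R^2 = ", round(max(cc), 3), ")")
    }
  }

  term_p <- function(current) {
    # KR F-test of each term against the model without it
    full <- lme4::lmer(
      as.formula(paste("emd ~", paste(current, collapse = " + "),
                       "+ (1 | nest)")),
      data = d, weights = d$weight, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    purrr::map_dfr(current, function(v) {
      rest <- setdiff(current, v)
      rhs <- if (length(rest)) paste(rest, collapse = " + ") else "1"
      red <- lme4::lmer(
        as.formula(paste("emd ~", rhs, "+ (1 | nest)")),
        data = d, weights = d$weight, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore"))
      kr <- suppressMessages(pbkrtest::KRmodcomp(full, red))
      st <- kr$test["Ftest", ]
      est <- lme4::fixef(full)[[v]]
      tibble::tibble(variable = v, estimate = est, F = st$stat,
                     ndf = st$ndf, ddf = st$ddf, p = st$p.value)
    })
  }

  current <- keep
  dropped <- tibble::tibble(step = integer(), variable = character(),
                            p = numeric())
  term_table <- tibble::tibble()
  step <- 0L
  while (length(current) > 0) {
    tt <- suppressWarnings(term_p(current))
    worst <- which.max(tt$p)
    if (tt$p[worst] <= alpha) {
      term_table <- dplyr::bind_rows(term_table, tt)
      break
    }
    step <- step + 1L
    dropped <- dplyr::bind_rows(dropped,
                                tibble::tibble(step = step,
                                               variable = tt$variable[worst],
                                               p = tt$p[worst]))
    term_table <- dplyr::bind_rows(term_table, tt[worst, ])
    current <- setdiff(current, tt$variable[worst])
  }

  final <- if (length(current)) {
    suppressWarnings(lme4::lmer(
      as.formula(paste("emd ~", paste(current, collapse = " + "),
                       "+ (1 | nest)")),
      data = d, weights = d$weight, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
  } else NULL

  structure(
    list(model = final, retained = current, dropped = dropped,
         term_table = term_table, alpha = alpha),
    class = "pf_cov_fit"
  )
}

#' @export
print.pf_cov_fit <- function(x, ...) {
  cat("<pf_cov_fit> retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Simulate EMD-like lag records from the crossed random-effects model
#'
#' Draws records directly from the generative model the lag analysis assumes:
#' a grand mean plus nest, male-UD and female-UD random intercepts and
#' residual noise, with an optional additive shift per lag class. Useful for
#' calibrating the type-I error and power of [fit_lag_model()] without
#' running the full movement pipeline.
#'
#' @param n_nests Number of nests.
#' @param n_windows Windows per parent per nest-day (8 hourly windows by
#'   default).
#' @param max_lag Maximum absolute lag in the table.
#' @param mean_emd Grand mean EMD (m).
#' @param sd_nest,sd_ud,sd_resid Standard deviations of the nest effect, the
#'   UD effects (male and female) and the residual (m).
#' @param lag_effect Optional named numeric vector of per-lag shifts (names
#'   are signed lags); e.g. `c("0" = -10)` depresses lag 0 by 10 m.
#' @param weights Either a single value or `"random"` for availability-like
#'   Beta(8, 2) weights.
#' @param seed Integer seed.
#' @return A `pf_lag_table`.
#' @export
simulate_lag_records <- function(n_nests = 8, n_windows = 8, max_lag = 7,
                                 mean_emd = 60, sd_nest = 8, sd_ud = 10,
                                 sd_resid = 12, lag_effect = NULL,
                                 weights = 1, seed = 1L) {
  local_seed(substream(seed, "reps"), {
    recs <- purrr::map_dfr(seq_len(n_nests), function(n) {
      nid <- sprintf("nest%02d", n)
      bn <- rnorm(1, 0, sd_nest)
      bm <- rnorm(n_windows, 0, sd_ud)
      bf <- rnorm(n_windows, 0, sd_ud)
      g <- tidyr::expand_grid(male_window = 0:(n_windows - 1),
                              female_window = 0:(n_windows - 1))
      g <- g[abs(g$female_window - g$male_window) <= max_lag, ]
      lag <- g$female_window - g$male_window
      eff <- if (is.null(lag_effect)) 0 else {
        e <- lag_effect[as.character(lag)]
        ifelse(is.na(e), 0, e)
      }
      w <- if (identical(weights, "random")) {
        rbeta_w <- stats::rbeta(nrow(g), 8, 2)
        pmax(rbeta_w, 0.1)
      } else rep(weights, nrow(g))
      tibble::tibble(
        nest = nid, day = 1L,
        male_window = g$male_window, female_window = g$female_window,
        male_ud_id = paste0(nid, "_m", g$male_window),
        female_ud_id = paste0(nid, "_f", g$female_window),
        lag = as.integer(lag),
        emd = pmax(mean_emd + bn + bm[g$male_window + 1] +
                     bf[g$female_window + 1] + eff +
                     rnorm(nrow(g), 0, sd_resid / sqrt(w)), 0.1),
        weight = w
      )
    })
    class(recs) <- c("pf_lag_table", class(recs))
    recs
  })
}
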