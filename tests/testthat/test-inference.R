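test_that("the lag F-test numerator df is the lag class count minus one", {
  recs <- simulate_lag_records(n_nests = 3, n_windows = 8, max_lag = 7,
                               seed = 2)
  fit <- fit_lag_model(recs)
  expect_equal(as.integer(fit$ndf), 14L)
  recs5 <- simulate_lag_records(n_nests = 3, n_windows = 8, max_lag = 5,
                                seed = 2)
  expect_equal(as.integer(fit_lag_model(recs5)$ndf), 10L)
})

test_that("unit weights reproduce the unweighted fit", {
  recs <- simulate_lag_records(n_nests = 3, seed = 4, weights = 1)
  fit <- fit_lag_model(recs)
  d <- fit$records
  d$lag_f <- factor(d$lag)
  un <- lme4::lmer(emd ~ lag_f + (1 | nest) + (1 | male_ud_id) +
                     (1 | female_ud_id), data = d, REML = TRUE)
  expect_equal(unname(lme4::fixef(fit$model)), unname(lme4::fixef(un)),
               tolerance = 1e-6)
})

test_that("degenerate record sets are rejected", {
  recs <- simulate_lag_records(n_nests = 2, seed = 1)
  one <- recs[recs$lag == 0, ]
  expect_error(fit_lag_model(one), "lag classes")
  bad <- recs; bad$weight[1] <- 0
  expect_error(fit_lag_model(bad))
})

test_that("a depressed lag-0 class earns its own post-hoc letter group", {
  recs <- simulate_lag_records(n_nests = 8, seed = 7, sd_resid = 8,
                               lag_effect = c("0" = -25))
  fit <- fit_lag_model(recs)
  expect_lt(fit$p, 0.05)
  ph <- posthoc_lags(fit)
  g0 <- ph$group[ph$lag == 0]
  others <- ph$group[ph$lag != 0]
  shared <- vapply(others, function(g) {
    any(strsplit(g0, "")[[1]] %in% strsplit(g, "")[[1]])
  }, logical(1))
  expect_false(any(shared))
})

test_that("under the null all lag classes usually share a letter", {
  share <- vapply(1:10, function(s) {
    fit <- fit_lag_model(simulate_lag_records(n_nests = 4, seed = 100 + s))
    ph <- posthoc_lags(fit)
    common <- Reduce(intersect, strsplit(ph$group, ""))
    length(common) > 0
  }, logical(1))
  expect_gte(mean(share), 0.9)
})

test_that("compact letter display handles corner cases", {
  cld_letters <- getFromNamespace("cld_letters", "pairforage")
  # single class
  expect_equal(cld_letters(matrix(TRUE, 1, 1), 1), "a")
  # all mutually different: distinct letters
  ns <- diag(3) == 1
  expect_equal(sort(cld_letters(ns, 1:3)), c("a", "b", "c"))
  # none different: one shared letter
  expect_equal(unique(cld_letters(matrix(TRUE, 3, 3), 1:3)), "a")
})

test_that("calibrated lag-0 depression is detected in most 8-pair datasets", {
  # lag-0 mean 20% below the lagged mean
  ps <- vapply(1:25, function(s) {
    recs <- simulate_lag_records(n_nests = 8, mean_emd = 60, sd_resid = 12,
                                 lag_effect = c("0" = -12), seed = 500 + s,
                                 weights = "random")
    fit_lag_model(recs)$p
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.9)
})

test_that("backward selection keeps real effects and drops null covariates", {
  gen <- function(seed, beta_chicks = 0) {
    local({
      set.seed(seed)
      purrr::map_dfr(1:8, function(n) {
        nc <- sample(4:10, 1)
        tibble::tibble(
          nest = sprintf("n%02d", n), hour = 0:7, day = sample(10:25, 1),
          n_chicks = nc, chick_age = sample(9:13, 1),
          emd = 50 + rnorm(1, 0, 6) + beta_chicks * nc + rnorm(8, 0, 8),
          weight = 1
        )
      })
    })
  }
  retained <- vapply(1:10, function(s) {
    f <- fit_covariate_model(gen(s, beta_chicks = 6))
    "n_chicks" %in% f$retained &&
      f$term_table$estimate[f$term_table$variable == "n_chicks"][1] > 0
  }, logical(1))
  expect_gte(mean(retained), 0.9)
  # with 4 null covariates the empty-model rate is ~0.95^4 = 0.81
  empty <- vapply(1:20, function(s) {
    length(fit_covariate_model(gen(400 + s))$retained) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.75)
})

test_that("collinear covariates abort with a diagnostic", {
  d <- tibble::tibble(
    nest = rep(sprintf("n%d", 1:6), each = 4),
    hour = rep(0:3, 6), day = rep(1:6, each = 4)
  )
  d$n_chicks <- d$day * 2          # R^2 = 1 with day
  d$chick_age <- 10
  d$emd <- 50 + rnorm(nrow(d), 0, 5)
  d$weight <- 1
  expect_error(fit_covariate_model(d), "collinear")
})

test_that("a lone significant covariate is retained by the stopping rule", {
  set.seed(42)
  d <- purrr::map_dfr(1:8, function(n) {
    x <- rnorm(8)
    tibble::tibble(nest = sprintf("n%02d", n), hour = 0:7,
                   day = x, emd = 50 + 3 * x + rnorm(8, 0, 6), weight = 1)
  })
  f <- fit_covariate_model(d, covariates = "day")
  expect_equal(f$retained, "day")
  expect_lt(tidy(f)$p[1], 0.05)
})
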