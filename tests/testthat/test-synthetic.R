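# Synthetic-cohort generator: reproducibility, calibration to the study
# marginals, degenerate configs, the fixture cohort, and epoch streams.

test_that("identical seed and config reproduce the cohort exactly", {
  cfg <- cohort_config(n = 80)
  a <- simulate_cohort(cfg, seed = 404)
  b <- simulate_cohort(cfg, seed = 404)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 405)
  expect_false(identical(a, c2))
})

test_that("zero log-ratio covariance collapses every participant to the mean composition", {
  cfg <- cohort_config(n = 25, logratio_cov = diag(1e-24, 3))
  d <- simulate_cohort(cfg, seed = 1)
  m <- as.matrix(d[, BEHAVIOURS])
  expect_equal(m, matrix(cfg$mean_composition, 25, 4, byrow = TRUE,
                         dimnames = dimnames(m)),
               tolerance = 1e-6)
})

test_that("sample geometric mean converges to the configured mean composition", {
  cfg <- cohort_config(n = 10000)
  d <- simulate_cohort(cfg, seed = 2024)
  gm <- comp_gmean(d)
  rel <- abs(gm - cfg$mean_composition) / cfg$mean_composition
  expect_true(all(rel < 0.02))
})

test_that("default calibration matches the published marginals", {
  cfg <- cohort_config()
  d <- simulate_cohort(cfg, seed = 77)
  expect_equal(nrow(d), 410L)
  expect_true(abs(mean(d$wemwbs) - 53.75) < 1.5)   # one-cohort check
  expect_true(abs(sd(d$wemwbs) - 8.43) < 1.5)
  expect_true(all(d$wemwbs >= 14 & d$wemwbs <= 70))

  v <- variation_matrix(d)
  off <- v[upper.tri(v)]
  # pairwise log-ratio variances bracket the published 0.103-0.550 range
  expect_lt(min(off), 0.16)
  expect_gt(max(off), 0.45)

  expect_true(abs(mean(d$sex == "female") - 0.71) < 0.08)
  expect_true(abs(mean(d$age) - 71.3) < 1.5)
})

test_that("the generator's behaviour effects are one consistent ILR vector", {
  cfg <- cohort_config(n = 200)
  # on a noiseless cohort built from beta_true, the four first-pivot
  # behaviour coefficients recover behaviour_effects exactly
  d <- simulate_cohort(cfg, seed = 66)
  z <- ilr(as.matrix(d[, BEHAVIOURS]))
  d$wemwbs <- drop(50 + z %*% cfg$beta_true)
  b <- suppressWarnings(behaviour_betas(coda_lm(wemwbs ~ 1, d)))
  expect_equal(b$beta, c(-2.17, -0.43, 1.96, 0.64), tolerance = 1e-6)
  expect_error(cohort_config(behaviour_effects = c(tst = 1, sb = 1,
                                                   lpa = 1, mvpa = 1)),
               "sum to ~0")
})

test_that("a null generator yields near-nominal rejection of the first-pivot test", {
  ncfg <- cohort_config(n = 410, beta_true = c(0, 0, 0))
  rej <- vapply(1:120, function(r) {
    d <- simulate_cohort(ncfg, seed = 7000 + r)
    f <- fit_wellbeing_models(d, models = 1)$model1
    summary(f$lm)$coefficients[2, 4] <= 0.05
  }, logical(1))
  # binomial(120, 0.05): mean 6, sd 2.4
  expect_true(sum(rej) <= 14)
})

test_that("confounding switch makes covariate adjustment matter", {
  base <- simulate_cohort(cohort_config(n = 2000), seed = 55)
  conf <- simulate_cohort(cohort_config(n = 2000, confound = TRUE,
                                        covariate_effects =
                                          c(age = -2, female = -1)),
                          seed = 55)
  gap <- function(d) {
    f1 <- behaviour_betas(fit_wellbeing_models(d, models = 1)$model1)
    f2 <- behaviour_betas(fit_wellbeing_models(d, models = 2)$model2)
    max(abs(f1$beta - f2$beta))
  }
  expect_gt(gap(conf), gap(base))
})

test_that("wemwbs_items spreads totals into valid items that re-score exactly", {
  scores <- c(14L, 70L, 42L, 53L, 69L)
  items <- wemwbs_items(scores)
  expect_true(all(items >= 1 & items <= 5))
  expect_equal(score_wemwbs(items), scores)
  expect_error(wemwbs_items(13), "14..70")
})

test_that("the fixture cohort is deterministic with the constructed anomalies", {
  f1 <- fixture_cohort()
  expect_identical(f1, fixture_cohort())
  expect_equal(nrow(f1), 12L)
  zr <- check_zeros(f1[, BEHAVIOURS])
  expect_equal(sum(zr), 1L)            # exactly one raw zero (MVPA)
  expect_equal(unname(zr[["mvpa"]]), 1L)
  expect_equal(sum(f1$n_valid_days < 4), 1L)

  a <- fixture_analysis_cohort()
  expect_equal(nrow(a), 11L)           # "included 11 of 12"
  expect_true(all(as.matrix(a[, BEHAVIOURS]) > 0))
  expect_equal(unname(rowSums(a[, BEHAVIOURS])), rep(1440, 11))
})

test_that("generated epoch streams round-trip through preprocessing", {
  set.seed(314)
  targets <- c(tst = 339, sb = 832.8, lpa = 154.8, mvpa = 113.4)
  st <- simulate_epoch_stream(targets, days = 6)
  ds <- accel_daily_summaries(st)
  expect_equal(nrow(ds), 6L)
  for (b in c("tst", "sb", "lpa", "mvpa")) {
    expect_true(all(abs(ds[[paste0(b, "_min")]] - round(targets[[b]])) <= 5))
  }
  pc <- participant_compositions(ds)
  expect_true(pc$included)
  expect_equal(sum(pc[, BEHAVIOURS]), 1440)
})

test_that("a measured cohort applies the exclusion filter at the configured rate", {
  d <- simulate_cohort(cohort_config(n = 12), seed = 8)
  res <- simulate_measured_cohort(d, n_short = 3, seed = 9)
  expect_equal(sum(res$compositions$included), 9L)
  expect_equal(sum(!res$compositions$included), 3L)
  excl <- res$compositions[!res$compositions$included, ]
  expect_true(all(excl$n_valid_days == 3L))
})
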