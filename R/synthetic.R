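# Synthetic cohorts: logistic-normal compositions calibrated to the study's
# published marginals (geometric-mean composition, pairwise log-ratio
# variance range, covariate frequencies, WEMWBS mean/SD), plus synthetic
# epoch streams that round-trip through the accelerometer pipeline, and a
# small deterministic fixture cohort.

# Default pairwise log-ratio variation targets. Only the extremes are
# published (0.103 for TST-SB, 0.550 for LPA-MVPA); intermediate entries
# are plausible values chosen once within that range (see the methods
# vignette) and verified to give a positive-definite ILR covariance.
.default_variation_targets <- function() {
  p <- BEHAVIOURS
  v <- matrix(0, 4, 4, dimnames = list(p, p))
  v["tst", "sb"] <- 0.103
  v["tst", "lpa"] <- 0.28
  v["tst", "mvpa"] <- 0.42
  v["sb", "lpa"] <- 0.24
  v["sb", "mvpa"] <- 0.38
  v["lpa", "mvpa"] <- 0.55
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  v
}

#' ILR covariance implied by a variation matrix
#'
#' Converts pairwise log-ratio variances into the covariance of the ILR
#' coordinates under `sbp`, via the centred log-ratio covariance
#' `Gamma = -0.5 * G T G` (G the centring projector). The input must be a
#' valid variation matrix (the result is checked for positive
#' definiteness).
#'
#' @param variation D x D symmetric matrix of log-ratio variances.
#' @param sbp SBP sign matrix (default 4-part pivot 1).
#' @return (D-1) x (D-1) positive-definite covariance matrix.
#' @export
ilr_cov_from_variation <- function(variation, sbp = sbp_pivot(4L, 1L)) {
  D <- ncol(variation)
  G <- diag(D) - matrix(1 / D, D, D)
  Gamma <- -0.5 * G %*% variation %*% G
  V <- ilr_basis(sbp)
  Sigma <- t(V) %*% Gamma %*% V
  Sigma <- (Sigma + t(Sigma)) / 2
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("variation matrix does not yield a positive-definite ILR covariance")
  }
  Sigma
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the generator emulates:
#' n = 410 analysed participants; geometric-mean composition
#' (5.65, 13.88, 2.58, 1.89) h of TST/SB/LPA/MVPA; log-ratio covariance
#' derived from pairwise variation targets spanning 0.103-0.550; covariate
#' frequencies from the published demographics table; WEMWBS mean 53.75 and
#' SD 8.43 truncated to \[14, 70\]; composition effects on well-being
#' matching the unadjusted per-behaviour coefficients (-2.17, -0.43, 1.96,
#' 0.64, summing to zero as one ILR effect vector requires).
#'
#' @param n number of participants.
#' @param mean_composition named minutes vector (closed to 1440 internally).
#' @param variation_targets 4 x 4 pairwise log-ratio variance targets; used
#'   to derive `logratio_cov` when that is `NULL`.
#' @param logratio_cov 3 x 3 ILR covariance (pivot-1 basis); overrides
#'   `variation_targets` when given.
#' @param behaviour_effects named per-behaviour first-pivot coefficients
#'   (must sum to ~0); used to derive `beta_true` when that is `NULL`.
#' @param beta_true length-3 ILR (pivot-1) effect vector on the WEMWBS.
#' @param covariate_effects optional named vector of outcome effects:
#'   `age` (points per SD of age) and `female` (points). Default none.
#' @param wemwbs_mean,wemwbs_sd target score mean and SD.
#' @param age_mean,age_sd age distribution (years), truncated to \[55, 95\].
#' @param noise_sd residual SD; by default derived so that the marginal
#'   score SD matches `wemwbs_sd` given the composition signal.
#' @param covariate_marginals list of category probability tables.
#' @param confound if `TRUE`, age and sex shift the ILR mean so that
#'   adjustment changes the estimates (default `FALSE`: covariates
#'   independent of the composition).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(
    n = 410,
    mean_composition = c(tst = 5.65, sb = 13.88, lpa = 2.58,
                         mvpa = 1.89) * 60,
    variation_targets = .default_variation_targets(),
    logratio_cov = NULL,
    behaviour_effects = c(tst = -2.17, sb = -0.43, lpa = 1.96, mvpa = 0.64),
    beta_true = NULL,
    covariate_effects = c(age = 0, female = 0),
    wemwbs_mean = 53.75, wemwbs_sd = 8.43,
    age_mean = 71.3, age_sd = 6.3,
    noise_sd = NULL,
    covariate_marginals = list(
      sex = c(male = 120, female = 290),
      education = c(low = 183, medium = 133, high = 82),
      marital = c("married/cohabitant" = 315, single = 95),
      professional = c(active = 17, inactive = 389),
      smoking = c(no = 390, yes = 14),
      chronic = c(no = 222, yes = 160, missing = 29)
    ),
    confound = FALSE) {
  mean_composition <- closure(mean_composition[BEHAVIOURS], total = 1440)
  sbp <- sbp_pivot(4L, 1L)
  if (is.null(logratio_cov)) {
    logratio_cov <- ilr_cov_from_variation(variation_targets, sbp)
  }
  if (is.null(beta_true)) {
    if (abs(sum(behaviour_effects)) > 0.05) {
      stop("behaviour_effects must sum to ~0: the four first-pivot ",
           "coefficients are linear images of one (D-1)-vector")
    }
    # first-pivot coefficient b_k relates to the clr coefficient a_k by
    # b_k = (2/sqrt(3)) a_k for D = 4
    a <- behaviour_effects[BEHAVIOURS] * sqrt(3) / 2
    a <- a - mean(a)  # exact clr centring
    beta_true <- drop(t(ilr_basis(sbp)) %*% a)
  }
  signal_var <- drop(t(beta_true) %*% logratio_cov %*% beta_true)
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(max(wemwbs_sd^2 - signal_var, 1))
  }
  covariate_marginals <- lapply(covariate_marginals, function(p) p / sum(p))
  structure(list(
    n = as.integer(n), mean_composition = mean_composition,
    logratio_cov = logratio_cov, beta_true = beta_true,
    covariate_effects = covariate_effects,
    wemwbs_mean = wemwbs_mean, wemwbs_sd = wemwbs_sd,
    age_mean = age_mean, age_sd = age_sd, noise_sd = noise_sd,
    covariate_marginals = covariate_marginals, confound = confound,
    sbp = sbp
  ), class = "cohort_config")
}

.sample_factor <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Simulate a participant cohort
#'
#' Draws ILR coordinates from a multivariate normal centred at the ILR of
#' the mean composition, inverts them to the simplex (logistic-normal
#' compositions), samples covariates from the configured marginals, and
#' builds WEMWBS scores as
#' `round(intercept + ilr' beta_true + covariate effects + noise)` clamped
#' to \[14, 70\]. Fully reproducible from `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @return data frame with `participant_id`, composition columns
#'   `tst, sb, lpa, mvpa` (minutes, closed to 1440), covariates, and
#'   `wemwbs`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n
  mu <- ilr(config$mean_composition, config$sbp)

  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 55), 95)
  cm <- config$covariate_marginals
  sex <- .sample_factor(n, cm$sex)
  education <- .sample_factor(n, cm$education)
  marital <- .sample_factor(n, cm$marital)
  professional <- .sample_factor(n, cm$professional)
  smoking <- .sample_factor(n, cm$smoking)
  chronic <- .sample_factor(n, cm$chronic)

  z <- MASS::mvrnorm(n, mu = mu, Sigma = config$logratio_cov)
  if (n == 1L) z <- matrix(z, nrow = 1L)
  if (isTRUE(config$confound)) {
    # age and sex shift the compositional mean: older and female
    # participants drift toward more sleep/sedentary time
    shift <- 0.15 * (age - config$age_mean) / config$age_sd +
      0.10 * (sex == "female")
    z[, 1L] <- z[, 1L] + shift
    z[, 2L] <- z[, 2L] + 0.5 * shift
  }
  comp <- ilr_inv(z, config$sbp, total = 1440)
  colnames(comp) <- BEHAVIOURS

  eff <- config$covariate_effects
  cov_eta <- eff[["age"]] * (age - config$age_mean) / config$age_sd +
    eff[["female"]] * (sex == "female")
  intercept <- config$wemwbs_mean - sum(mu * config$beta_true)
  eta <- intercept + drop(z %*% config$beta_true) + cov_eta
  score <- round(eta + stats::rnorm(n, 0, config$noise_sd))
  score <- pmin(pmax(score, 14), 70)

  out <- data.frame(
    participant_id = sprintf("S%04d", seq_len(n)),
    comp,
    age = age, sex = sex, education = education, marital = marital,
    professional = professional, smoking = smoking,
    chronic = as.character(chronic),
    wemwbs = as.integer(score),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Distribute WEMWBS totals over 14 items
#'
#' Inverse of [score_wemwbs()] up to the item split: spreads each total
#' score (14-70) across 14 items in 1..5 as evenly as possible. Used by the
#' generator's item-level mode.
#'
#' @param score integer vector of totals in 14..70.
#' @return n x 14 integer matrix of item responses whose row sums equal
#'   `score`.
#' @export
wemwbs_items <- function(score) {
  if (any(score < 14 | score > 70)) stop("scores must lie in 14..70")
  t(vapply(as.integer(score), function(s) {
    base <- s %/% 14L
    rem <- s %% 14L
    c(rep(base + 1L, rem), rep(base, 14L - rem))
  }, integer(14L)))
}

#' Deterministic 12-participant fixture cohort
#'
#' A tiny hand-specified cohort for unit tests and examples: eleven
#' participants with enough valid wear days, one (`F11`) with only 3 valid
#' days (excluded by the 4-day rule), and one (`F12`) with a raw zero in
#' MVPA (exercises the zero-handling path). Compositions are plain numbers,
#' not random draws, so expected values are hand-checkable.
#'
#' @return data frame with `participant_id`, `n_valid_days`, raw behaviour
#'   minutes `tst, sb, lpa, mvpa`, covariates and `wemwbs`.
#' @export
fixture_cohort <- function() {
  data.frame(
    participant_id = sprintf("F%02d", 1:12),
    n_valid_days = c(6L, 6L, 5L, 6L, 4L, 6L, 5L, 6L, 4L, 6L, 3L, 5L),
    tst = c(330, 360, 300, 345, 380, 310, 350, 340, 325, 365, 340, 355),
    sb  = c(840, 800, 880, 830, 760, 860, 790, 845, 835, 780, 830, 850),
    lpa = c(160, 170, 140, 150, 180, 150, 175, 140, 165, 185, 155, 175),
    mvpa = c(110, 110, 120, 115, 120, 120, 125, 115, 115, 110, 115, 0),
    age = c(65, 72, 78, 69, 81, 66, 74, 70, 76, 62, 71, 68),
    sex = c("female", "male", "female", "female", "male", "female",
            "female", "male", "female", "female", "male", "female"),
    education = c("low", "medium", "low", "high", "low", "medium", "high",
                  "low", "medium", "low", "high", "medium"),
    marital = c("married/cohabitant", "married/cohabitant", "single",
                "married/cohabitant", "single", "married/cohabitant",
                "married/cohabitant", "single", "married/cohabitant",
                "married/cohabitant", "single", "married/cohabitant"),
    professional = c("inactive", "inactive", "inactive", "active",
                     "inactive", "inactive", "inactive", "inactive",
                     "inactive", "active", "inactive", "inactive"),
    smoking = c("no", "no", "no", "no", "yes", "no", "no", "no", "no",
                "no", "no", "no"),
    chronic = c("no", "yes", "no", "no", "yes", "no", "missing", "no",
                "yes", "no", "no", "no"),
    wemwbs = c(55L, 52L, 48L, 60L, 45L, 57L, 58L, 50L, 51L, 62L, 53L, 56L),
    stringsAsFactors = FALSE
  )
}

#' Analysis-ready fixture cohort
#'
#' Applies the inclusion and zero-handling steps to [fixture_cohort()]:
#' drops the 3-valid-day participant, replaces the single raw zero by 1 min
#' (multiplicative replacement) and closes each row to 1440 min.
#'
#' @return 11-row data frame ready for [coda_lm()].
#' @export
fixture_analysis_cohort <- function() {
  d <- fixture_cohort()
  d <- d[d$n_valid_days >= 4L, , drop = FALSE]
  m <- as.matrix(d[, BEHAVIOURS])
  if (!attr(check_zeros(m), "proceed")) {
    m <- replace_zeros(m, delta = 1)
  }
  d[, BEHAVIOURS] <- closure(m, total = 1440)
  rownames(d) <- NULL
  d
}

# ---- synthetic epoch streams -------------------------------------------

# Counts for one calendar day (1440 one-minute epochs) hitting the target
# behaviour minutes. Sleep epochs carry small non-zero counts (below the
# sleep-score threshold but breaking zero runs); waking behaviours carry
# counts inside their cut-point bands. A "short" day replaces most waking
# time with a long zero block (device off), invalidating the day.
.build_day_counts <- function(targets, config, short = FALSE) {
  cp <- config$cutpoints
  m <- round(targets[BEHAVIOURS])
  m["sb"] <- 1440 - m[["tst"]] - m[["lpa"]] - m[["mvpa"]]
  if (any(m < 1)) stop("target minutes infeasible within a 1440-min day")
  sleep <- stats::runif(m[["tst"]], 5, 30)
  if (short) {
    off <- rep(0, 700)
    wake_sb <- 1440 - m[["tst"]] - 700
    if (wake_sb < 1) stop("short-day layout infeasible")
    sb <- stats::runif(wake_sb, 200, min(1500, cp$sb_upper))
    return(c(sleep, sb[1], off, sb[-1]))
  }
  sb1_n <- m[["sb"]] %/% 2
  sb <- stats::runif(m[["sb"]], 200, min(1500, cp$sb_upper))
  lpa <- stats::runif(m[["lpa"]], cp$sb_upper + 400, cp$lpa_upper - 50)
  mvpa <- stats::runif(m[["mvpa"]], cp$lpa_upper + 500, cp$lpa_upper + 4000)
  c(sleep, sb[seq_len(sb1_n)], lpa, mvpa, sb[-seq_len(sb1_n)])
}

#' Simulate an epoch stream for one participant
#'
#' Builds `days` calendar days of 60-s VM3 epochs whose behaviour-conditional
#' count regimes are arranged so that the preprocessing pipeline
#' ([accel_daily_summaries()]) recovers the participant's target daily
#' minutes to within a few minutes per behaviour. The first `short_days`
#' days are generated with a long device-off block so they fail the 10-h
#' waking wear rule.
#'
#' @param targets named minutes vector (`tst, sb, lpa, mvpa`), one day's
#'   targets; the same layout is used each day.
#' @param days number of consecutive calendar days (default 6, matching a
#'   6-day wear protocol).
#' @param short_days how many of the days are invalid short-wear days.
#' @param config accelerometer config ([accel_config()]).
#' @param participant_id id stamped on the rows.
#' @param start first epoch timestamp (midnight-aligned POSIXct).
#' @return data frame of epoch records (`participant_id`, `timestamp`,
#'   `vm3`).
#' @export
simulate_epoch_stream <- function(targets, days = 6L, short_days = 0L,
                                  config = accel_config(),
                                  participant_id = "P1",
                                  start = as.POSIXct("2019-03-04 00:00:00",
                                                     tz = "UTC")) {
  if (config$epoch_length_s != 60) {
    stop("the stream generator emits 60-s epochs")
  }
  counts <- unlist(lapply(seq_len(days), function(d) {
    .build_day_counts(targets, config, short = d <= short_days)
  }))
  data.frame(
    participant_id = participant_id,
    timestamp = start + 60 * (seq_along(counts) - 1L),
    vm3 = counts,
    stringsAsFactors = FALSE
  )
}

#' Simulate a measured cohort: epoch streams through the full pipeline
#'
#' For each participant of a target cohort, generates a 6-day epoch stream
#' ([simulate_epoch_stream()]), runs it through the preprocessing pipeline
#' and collects daily summaries and per-participant compositions. A chosen
#' number of participants receive fewer than `min_valid_days` valid days so
#' the exclusion filter is exercised (the study observed 410 of 453
#' participants surviving the 4-day rule).
#'
#' @param targets data frame with composition columns `tst, sb, lpa, mvpa`
#'   (one row per participant), e.g. from [simulate_cohort()].
#' @param n_short number of participants given only 3 valid days.
#' @param config accelerometer config.
#' @param seed RNG seed.
#' @param days days per participant (default 6).
#' @return list with `daily` (all daily summaries) and `compositions`
#'   (from [participant_compositions()]).
#' @export
simulate_measured_cohort <- function(targets, n_short = 0L,
                                     config = accel_config(), seed = 1L,
                                     days = 6L) {
  set.seed(seed)
  n <- nrow(targets)
  short <- rep(0L, n)
  if (n_short > 0L) {
    short[sample.int(n, n_short)] <- days - (config$min_valid_days - 1L)
  }
  ids <- if ("participant_id" %in% names(targets)) {
    targets$participant_id
  } else {
    sprintf("S%04d", seq_len(n))
  }
  daily <- vector("list", n)
  for (i in seq_len(n)) {
    stream <- simulate_epoch_stream(
      unlist(targets[i, BEHAVIOURS]), days = days, short_days = short[i],
      config = config, participant_id = ids[i])
    daily[[i]] <- accel_daily_summaries(stream, config)
  }
  daily <- do.call(rbind, daily)
  list(daily = daily,
       compositions = participant_compositions(
         daily, min_valid_days = config$min_valid_days))
}
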