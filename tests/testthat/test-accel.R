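# Accelerometer preprocessing: non-wear runs, sleep scoring, cut-point
# classification, daily summaries and the valid-day inclusion rule.

test_that("detect_nonwear handles the all-zero, all-positive and spiked-run cases", {
  expect_true(all(detect_nonwear(rep(0, 1440))))
  expect_false(any(detect_nonwear(rep(500, 1440))))

  # 120-min zero run with a single 1-min spike inside, window 90, tol 2:
  # the whole run (spike included) is non-wear
  vm3 <- c(rep(300, 50), rep(0, 60), 80, rep(0, 59), rep(300, 50))
  nw <- detect_nonwear(vm3, window_min = 90, spike_tolerance_min = 2)
  expect_true(all(nw[51:170]))
  expect_false(any(nw[c(1:50, 171:220)]))

  # a short zero run below the window is worn
  expect_false(any(detect_nonwear(c(rep(100, 10), rep(0, 89), rep(100, 10)),
                                  window_min = 90)))
})

test_that("detect_nonwear agrees with the interval-enumeration oracle", {
  set.seed(61)
  for (rep_i in 1:15) {
    n <- 250
    # sparse positives so that long zero runs occur
    vm3 <- ifelse(runif(n) < 0.12, rpois(n, 300), 0)
    got <- detect_nonwear(vm3, window_min = 30, spike_tolerance_min = 2)
    expect_identical(got, oracle_nonwear(vm3, win = 30, tol = 2))
  }
})

test_that("detect_nonwear rejects non-contiguous epoch streams", {
  ts <- as.POSIXct("2019-03-04 00:00:00", tz = "UTC") + 60 * c(0:10, 12)
  df <- data.frame(timestamp = ts, vm3 = rep(100, 12))
  expect_error(detect_nonwear(df), "non-contiguous")
})

test_that("score_sleep thresholds the weighted window sum with edge padding", {
  w <- c(0.12, 0.5, 1, 0.5, 0.12)
  expect_true(all(score_sleep(rep(0, 100), w, threshold = 50)))
  expect_false(any(score_sleep(rep(5000, 100), w, threshold = 50)))
  expect_error(score_sleep(rep(0, 10), weights = c(1, 1)), "odd length")

  # constructed sequence straddling the threshold vs brute-force sums
  x <- c(0, 30, 120, 0, 10, 400, 35, 0, 80, 15)
  expect_identical(score_sleep(x, w, threshold = 150),
                   oracle_sleep(x, w, threshold = 150))
  set.seed(71)
  for (i in 1:10) {
    x <- rpois(50, 60)
    expect_identical(score_sleep(x, w, threshold = 130),
                     oracle_sleep(x, w, threshold = 130))
  }
})

test_that("classify_epochs applies the label hierarchy and boundary conventions", {
  cp <- list(sb_upper = 1853, lpa_upper = 3940)
  lab <- function(vm3, wear = TRUE, sleep = FALSE) {
    as.character(classify_epochs(vm3, wear, sleep, cp))
  }
  expect_equal(lab(0), "SB")                      # wear + wake + 0 counts
  expect_equal(lab(cp$sb_upper), "SB")            # inclusive upper bound
  expect_equal(lab(cp$sb_upper + 1), "LPA")
  expect_equal(lab(cp$lpa_upper), "LPA")          # inclusive upper bound
  expect_equal(lab(cp$lpa_upper + 1), "MVPA")
  expect_equal(lab(10, sleep = TRUE), "TST")
  expect_equal(lab(5000, wear = FALSE, sleep = TRUE), "NONWEAR")  # dominates
})

test_that("summarize_day totals minutes and applies the inclusive 10-h rule", {
  labels <- factor(c(rep("SB", 600), rep("TST", 500), rep("LPA", 200),
                     rep("MVPA", 100), rep("NONWEAR", 40)),
                   levels = c("TST", "SB", "LPA", "MVPA", "NONWEAR"))
  d <- summarize_day(labels)
  expect_equal(d$sb_min, 600)
  expect_equal(d$waking_wear_min, 900)
  expect_equal(d$tst_min + d$sb_min + d$lpa_min + d$mvpa_min +
                 d$nonwear_min, 1440)
  expect_true(d$is_valid)

  # permuting epochs leaves the daily totals unchanged
  set.seed(81)
  expect_equal(summarize_day(sample(labels)), d)

  at_bound <- factor(rep(c("SB", "NONWEAR"), c(600, 840)),
                     levels = levels(labels))
  expect_true(summarize_day(at_bound)$is_valid)    # 600 min: inclusive
  below <- factor(rep(c("SB", "NONWEAR"), c(599, 841)),
                  levels = levels(labels))
  expect_false(summarize_day(below)$is_valid)
})

test_that("participant_compositions enforces the 4-valid-day rule and averages", {
  day <- function(id, valid, tst = 340, sb = 830, lpa = 155, mvpa = 115) {
    data.frame(participant_id = id, date = Sys.Date(),
               tst_min = tst, sb_min = sb, lpa_min = lpa, mvpa_min = mvpa,
               nonwear_min = 1440 - tst - sb - lpa - mvpa,
               waking_wear_min = if (valid) 1100 else 300,
               is_valid = valid)
  }
  d3 <- do.call(rbind, c(lapply(1:3, function(i) day("A", TRUE)),
                         list(day("A", FALSE))))
  d4 <- do.call(rbind, lapply(1:4, function(i) day("B", TRUE)))
  res <- participant_compositions(rbind(d3, d4))
  expect_false(res$included[res$participant_id == "A"])
  expect_true(res$included[res$participant_id == "B"])

  # identical valid days -> closure of that day's vector
  b <- res[res$participant_id == "B", BEHAVIOURS]
  expect_equal(unname(unlist(b)), unname(closure(c(340, 830, 155, 115))))

  # exclusion is monotone: removing a valid day never includes an excluded
  # participant
  fewer <- participant_compositions(rbind(d3[-1, ], d4))
  expect_false(fewer$included[fewer$participant_id == "A"])
})

test_that("the daily pipeline drops partial days and processes complete ones", {
  set.seed(91)
  targets <- c(tst = 339, sb = 832.8, lpa = 154.8, mvpa = 113.4)
  st <- simulate_epoch_stream(targets, days = 2)
  # truncate the final day: it must be dropped
  st_partial <- st[1:(1440 + 600), ]
  ds <- accel_daily_summaries(st_partial)
  expect_equal(nrow(ds), 1L)
  expect_true(ds$is_valid)
})

test_that("epoch CSV and YAML config round-trip through the readers", {
  st <- simulate_epoch_stream(c(tst = 400, sb = 800, lpa = 140, mvpa = 100),
                              days = 1)
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(participant_id = st$participant_id,
                       timestamp = format(st$timestamp,
                                          "%Y-%m-%dT%H:%M:%S"),
                       vm3 = st$vm3),
            csv, row.names = FALSE)
  back <- read_epochs(csv)
  expect_equal(back$vm3, st$vm3)
  expect_equal(back$timestamp, st$timestamp)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("cutpoints:", "  sb_upper: 100", "  lpa_upper: 2000",
               "nonwear:", "  window_min: 60"), yml)
  cfg <- read_accel_config(yml)
  expect_equal(cfg$cutpoints$sb_upper, 100)
  expect_equal(cfg$nonwear$window_min, 60)
  expect_equal(cfg$nonwear$spike_tolerance_min, 2)  # default retained

  writeLines(c("sleep:", "  weights: [1, 1]"), yml)
  expect_error(read_accel_config(yml), "odd length")
})
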