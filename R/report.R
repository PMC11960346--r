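# Report-shaped outputs: cohort description (demographics with per-category
# well-being, geometric-mean time use), per-behaviour association tables
# across the staged models, and focal substitution tables.

#' Describe a cohort: time use and demographics
#'
#' Computes (a) the geometric-mean time-use composition in hours/day and as
#' percentage of the 24-h day (percentages from unrounded minutes, so they
#' sum to 100), and (b) covariate category frequencies with the mean (SD)
#' WEMWBS score per category.
#'
#' @param data analysis cohort with composition columns `tst, sb, lpa,
#'   mvpa` (minutes), covariates, and a `wemwbs` column.
#' @param total closure constant in minutes (default 1440).
#' @return list with `time_use` (behaviour, minutes, hours, pct_of_day) and
#'   `demographics` (variable, category, n, pct, wemwbs_mean, wemwbs_sd).
#' @export
describe_cohort <- function(data, total = 1440) {
  gm <- comp_gmean(data, total = total)
  time_use <- data.frame(
    behaviour = toupper(BEHAVIOURS),
    minutes = as.numeric(gm),
    hours = as.numeric(gm) / 60,
    pct_of_day = 100 * as.numeric(gm) / total,
    stringsAsFactors = FALSE
  )
  vars <- intersect(c("sex", "education", "marital", "professional",
                      "smoking", "chronic"), names(data))
  demo <- list()
  for (v in vars) {
    x <- as.character(data[[v]])
    for (lev in unique(x)) {
      sel <- x == lev
      demo[[length(demo) + 1L]] <- data.frame(
        variable = v, category = lev, n = sum(sel),
        pct = 100 * mean(sel),
        wemwbs_mean = mean(data$wemwbs[sel]),
        wemwbs_sd = stats::sd(data$wemwbs[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if ("age" %in% names(data)) {
    demo[[length(demo) + 1L]] <- data.frame(
      variable = "age", category = sprintf("mean %.1f (sd %.1f)",
                                           mean(data$age),
                                           stats::sd(data$age)),
      n = nrow(data), pct = 100,
      wemwbs_mean = mean(data$wemwbs), wemwbs_sd = stats::sd(data$wemwbs),
      stringsAsFactors = FALSE)
  }
  list(time_use = time_use,
       demographics = do.call(rbind, demo))
}

#' Per-behaviour association table across models
#'
#' Stacks [behaviour_betas()] over a set of fitted models into the familiar
#' behaviours x models layout (coefficient, SE, p per behaviour; shared
#' R-squared and overall model p per model).
#'
#' @param fits named list of `coda_lm` fits, e.g. from
#'   [fit_wellbeing_models()].
#' @return data frame with `model`, `behaviour`, `beta`, `se`, `p`,
#'   `r_squared`, `model_p`, `n_used`.
#' @export
wellbeing_table <- function(fits) {
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, behaviour_betas(fits[[nm]]))
  }))
  rownames(out) <- NULL
  out
}

# The four public-health-focused 30-min reallocations.
.FOCAL_PAIRS <- data.frame(
  from = c("sb", "sb", "lpa", "sb"),
  to = c("lpa", "mvpa", "mvpa", "tst"),
  stringsAsFactors = FALSE
)

#' Focal substitution table across models
#'
#' Estimates the predicted well-being change (with CI) for a set of focal
#' reallocations -- by default the four 30-min reallocations from SB to LPA,
#' SB to MVPA, LPA to MVPA and SB to sleep -- under each fitted model.
#'
#' @param fits named list of `coda_lm` fits.
#' @param minutes reallocated duration (default 30).
#' @param pairs data frame with `from`, `to` columns (default the four
#'   focal pairs).
#' @param conf_level confidence level (default 0.95).
#' @return data frame with `model`, `from`, `to`, `minutes`, `delta`,
#'   `lwr`, `upr`, `significant`.
#' @export
substitution_table <- function(fits, minutes = 30, pairs = .FOCAL_PAIRS,
                               conf_level = 0.95) {
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      cbind(model = nm,
            substitute_time(f, pairs$from[i], pairs$to[i], minutes,
                            conf_level = conf_level))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Full substitution grids across models
#'
#' Runs [substitution_grid()] for each fitted model and stacks the results
#' with a `model` column; also returns the plot-ready long curve table.
#'
#' @param fits named list of `coda_lm` fits.
#' @param minutes duration grid (default 5-60 by 5).
#' @return list with `grid` (stacked grids) and `curves` (long table from
#'   [export_curves()]).
#' @export
substitution_report <- function(fits, minutes = seq(5, 60, by = 5)) {
  grids <- lapply(names(fits), function(nm) {
    g <- substitution_grid(fits[[nm]], minutes = minutes)
    cbind(model = nm, as.data.frame(g))
  })
  curves <- lapply(names(fits), function(nm) {
    export_curves(substitution_grid(fits[[nm]], minutes = minutes),
                  model = nm)
  })
  list(grid = do.call(rbind, grids), curves = do.call(rbind, curves))
}
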