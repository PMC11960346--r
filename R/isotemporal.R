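# Compositional isotemporal substitution: reallocate minutes between
# behaviours at a reference composition and predict the well-being
# difference, with delta-method confidence intervals from the fitted
# coefficient covariance.

#' Reallocate minutes between two behaviours
#'
#' Moves `minutes` from one part of a composition to another, leaving the
#' remaining parts and the 1440-min total unchanged.
#'
#' @param reference named composition vector (parts in minutes).
#' @param from,to behaviour names (distinct).
#' @param minutes duration to move (>= 0).
#' @return the adjusted composition.
#' @examples
#' reallocate(c(tst = 339, sb = 833, lpa = 155, mvpa = 113),
#'            from = "sb", to = "mvpa", minutes = 30)
#' @export
reallocate <- function(reference, from, to, minutes) {
  if (from == to) stop("'from' and 'to' must differ")
  if (!all(c(from, to) %in% names(reference))) {
    stop("behaviours must be named parts of the reference composition")
  }
  if (minutes < 0) stop("'minutes' must be non-negative")
  if (minutes >= reference[[from]]) {
    stop("infeasible reallocation: ", minutes, " min >= the ", from,
         " part (", signif(reference[[from]], 6), " min)")
  }
  out <- reference
  out[[from]] <- out[[from]] - minutes
  out[[to]] <- out[[to]] + minutes
  out
}

#' Predicted well-being change for one time reallocation
#'
#' Computes the model-predicted outcome difference between the reallocated
#' and the reference composition. Covariates are held fixed and cancel in
#' the difference, so the estimate is `t(d) %*% beta_ilr` with
#' `d = ilr(new) - ilr(reference)`; its confidence interval is the
#' delta-method interval `+/- t_(1-alpha/2, df) * sqrt(t(d) Sigma d)` using
#' the ILR block of the coefficient covariance and the fit's residual
#' degrees of freedom.
#'
#' @param object a [coda_lm()] fit.
#' @param from,to behaviour names (see [BEHAVIOURS]).
#' @param minutes minutes reallocated from `from` to `to`.
#' @param reference reference composition (named minutes vector); default is
#'   the geometric-mean composition of the analysed participants.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data frame: `from`, `to`, `minutes`, `delta`, `lwr`,
#'   `upr`, `significant` (CI excludes 0).
#' @export
substitute_time <- function(object, from, to, minutes, reference = NULL,
                            conf_level = 0.95) {
  if (is.null(reference)) reference <- substitution_reference(object)
  new_comp <- reallocate(reference, from, to, minutes)
  z_ref <- ilr(reference[object$parts], object$sbp)
  z_new <- ilr(new_comp[object$parts], object$sbp)
  d <- z_new - z_ref
  beta <- stats::coef(object$lm)[object$ilr_names]
  Sigma <- stats::vcov(object$lm)[object$ilr_names, object$ilr_names]
  delta <- sum(d * beta)
  se <- sqrt(drop(t(d) %*% Sigma %*% d))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, stats::df.residual(object$lm))
  lwr <- delta - tcrit * se
  upr <- delta + tcrit * se
  data.frame(from = from, to = to, minutes = minutes,
             delta = delta, lwr = lwr, upr = upr,
             significant = lwr > 0 | upr < 0,
             stringsAsFactors = FALSE)
}

#' Default substitution reference composition
#'
#' The geometric-mean composition of the participants used in the fit -- the
#' standard reference point for compositional substitution modelling.
#'
#' @param object a `coda_lm` fit.
#' @return named composition vector (minutes, summing to the fit's total).
#' @export
substitution_reference <- function(object) {
  stats::setNames(comp_gmean(object$comp, total = object$total),
                  object$parts)
}

#' Substitution estimates over a grid of durations
#'
#' Evaluates [substitute_time()] for every ordered pair of distinct
#' behaviours (12 pairs for 4 parts) and every duration in `minutes`
#' (default 5-60 min at 5-min steps: 144 estimates). Infeasible cells
#' (duration >= the donor part at the reference) are kept as rows with `NA`
#' estimates and a `reason`, never dropped silently.
#'
#' @inheritParams substitute_time
#' @param minutes vector of durations (default `seq(5, 60, by = 5)`).
#' @return data frame of class `"coda_substitution"` with columns `from`,
#'   `to`, `minutes`, `delta`, `lwr`, `upr`, `significant`, `feasible`,
#'   `reason`.
#' @export
substitution_grid <- function(object, minutes = seq(5, 60, by = 5),
                              reference = NULL, conf_level = 0.95) {
  if (is.null(reference)) reference <- substitution_reference(object)
  parts <- object$parts
  rows <- list()
  for (from in parts) for (to in parts) {
    if (from == to) next
    for (t_min in minutes) {
      row <- if (t_min < reference[[from]]) {
        cbind(substitute_time(object, from, to, t_min,
                              reference = reference,
                              conf_level = conf_level),
              feasible = TRUE, reason = NA_character_)
      } else {
        data.frame(from = from, to = to, minutes = t_min,
                   delta = NA_real_, lwr = NA_real_, upr = NA_real_,
                   significant = NA, feasible = FALSE,
                   reason = paste0(t_min, " min >= reference ", from,
                                   " part"),
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "conf_level") <- conf_level
  class(out) <- c("coda_substitution", "data.frame")
  out
}

#' Long-format substitution curves for plotting
#'
#' Reshapes a substitution grid into the long table behind the 12-panel
#' substitution-curve figure, adding the exact (0, 0) anchor for every pair.
#'
#' @param grid a [substitution_grid()] result.
#' @param model label recorded in the `model` column (default `""`).
#' @return data frame with `pair`, `from`, `to`, `minutes`, `delta`, `lwr`,
#'   `upr`, `model`, ordered by pair then duration.
#' @export
export_curves <- function(grid, model = "") {
  g <- as.data.frame(grid)
  pairs <- unique(g[, c("from", "to")])
  anchors <- data.frame(from = pairs$from, to = pairs$to, minutes = 0,
                        delta = 0, lwr = 0, upr = 0,
                        significant = FALSE, feasible = TRUE,
                        reason = NA_character_,
                        stringsAsFactors = FALSE)
  out <- rbind(anchors, g)
  out$pair <- paste(toupper(out$from), "→", toupper(out$to))
  out$model <- model
  out <- out[order(out$from, out$to, out$minutes),
             c("pair", "from", "to", "minutes", "delta", "lwr", "upr",
               "model")]
  rownames(out) <- NULL
  out
}

#' Plot substitution curves
#'
#' Draws the predicted well-being change (with confidence band) against the
#' reallocated duration, one panel per ordered behaviour pair.
#'
#' @param x a `coda_substitution` grid.
#' @param ... ignored.
#' @return invisibly, the long curve table.
#' @export
plot.coda_substitution <- function(x, ...) {
  curves <- export_curves(x)
  pairs <- unique(curves$pair)
  old <- graphics::par(mfrow = c(4, 3), mar = c(3.5, 3.5, 2, 1),
                       mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  ylim <- range(curves$lwr, curves$upr, na.rm = TRUE)
  for (p in pairs) {
    d <- curves[curves$pair == p & !is.na(curves$delta), ]
    plot(d$minutes, d$delta, type = "l", ylim = ylim,
         xlab = "minutes reallocated", ylab = "Δ well-being", main = p)
    graphics::polygon(c(d$minutes, rev(d$minutes)), c(d$lwr, rev(d$upr)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(d$minutes, d$delta)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(curves)
}
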