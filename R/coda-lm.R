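# Linear models of well-being on ILR pivot coordinates: the central fitting
# function coda_lm() and its S3 methods, plus the staged covariate sets
# (models 1-3) and the per-behaviour coefficient table obtained by pivot
# rotation.

#' Covariate sets for the staged adjustment models
#'
#' Model 1 is unadjusted; model 2 adds age, sex, education, marital status
#' and professional activity; model 3 additionally adjusts for smoking and
#' chronic conditions.
#'
#' @param model_id 1, 2 or 3.
#' @return character vector of covariate column names (empty for model 1).
#' @export
model_covariates <- function(model_id) {
  model_id <- as.integer(model_id)
  base <- c("age", "sex", "education", "marital", "professional")
  switch(model_id,
         character(0),
         base,
         c(base, "smoking", "chronic"))
}

# Reference levels, first level = reference in dummy coding.
.COVARIATE_LEVELS <- list(
  sex = c("male", "female"),
  education = c("low", "medium", "high"),
  marital = c("married/cohabitant", "single"),
  professional = c("active", "inactive"),
  smoking = c("no", "yes"),
  chronic = c("no", "yes")
)

# Coerce covariate columns to factors with the canonical reference levels;
# chronic == "missing" becomes NA (dropped listwise only where chronic is in
# the model).
.prepare_covariates <- function(data, covs) {
  for (v in intersect(covs, names(.COVARIATE_LEVELS))) {
    x <- as.character(data[[v]])
    if (v == "chronic") x[x == "missing"] <- NA
    bad <- !is.na(x) & !(x %in% .COVARIATE_LEVELS[[v]])
    if (any(bad)) {
      stop("unknown level(s) in '", v, "': ",
           paste(unique(x[bad]), collapse = ", "))
    }
    data[[v]] <- factor(x, levels = .COVARIATE_LEVELS[[v]])
  }
  data
}

#' Fit a compositional linear model of well-being
#'
#' Regresses an outcome (ordinarily the WEMWBS score) on the three ILR pivot
#' coordinates of the 4-part time-use composition plus any covariates, by
#' ordinary least squares. The composition columns are closed and
#' transformed internally; the coordinate with `pivot` as numerator carries
#' the "this behaviour relative to all others" interpretation.
#'
#' @param formula model formula whose left side is the outcome column and
#'   whose right side lists the covariates (use `~ 1` RHS, or
#'   [model_covariates()], for the unadjusted model). The ILR coordinates
#'   are added automatically and must not appear in the formula.
#' @param data data frame containing the outcome, the composition columns
#'   named `tst, sb, lpa, mvpa` (minutes), and any covariates.
#' @param pivot which behaviour (index into [BEHAVIOURS], or its name) sits
#'   in the first pivot coordinate. Default 1 (`tst`).
#' @param parts names of the composition columns (default [BEHAVIOURS]).
#' @param total closure constant, minutes (default 1440).
#' @return object of class `"coda_lm"`: a list with the underlying `lm`
#'   fit (`$lm`), the SBP sign matrix (`$sbp`), `pivot`, `parts`, `total`,
#'   the analysed data (`$model_data`, after listwise deletion), `n_used`,
#'   and the closed composition matrix of analysed rows (`$comp`).
#' @seealso [behaviour_betas()], [substitute_time()], [substitution_grid()]
#' @export
coda_lm <- function(formula, data, pivot = 1L, parts = BEHAVIOURS,
                    total = 1440) {
  if (is.character(pivot)) pivot <- match(pivot, parts)
  pivot <- as.integer(pivot)
  if (is.na(pivot) || pivot < 1L || pivot > length(parts)) {
    stop("'pivot' must name or index one of: ", paste(parts, collapse = ", "))
  }
  if (!all(parts %in% names(data))) {
    stop("data lacks composition columns: ",
         paste(setdiff(parts, names(data)), collapse = ", "))
  }
  covs <- attr(stats::terms(formula, data = data), "term.labels")
  if (any(covs %in% parts) || any(grepl("^ilr[0-9]+$", covs))) {
    stop("composition parts/ILR coordinates are added automatically; ",
         "do not put them in the formula")
  }
  response <- all.vars(formula)[1L]

  data <- .prepare_covariates(data, covs)
  comp_raw <- as.matrix(data[, parts, drop = FALSE])
  if (anyNA(comp_raw)) stop("missing values in composition columns")
  if (any(comp_raw <= 0)) {
    stop("non-positive composition parts; run check_zeros()/replace_zeros()")
  }

  keep <- stats::complete.cases(data[, c(response, covs), drop = FALSE])
  data_used <- data[keep, , drop = FALSE]
  for (v in covs) {
    if (is.factor(data_used[[v]]) &&
        length(unique(stats::na.omit(data_used[[v]]))) < 2L) {
      stop("rank-deficient design; collinear columns: ", v,
           " (single observed level)")
    }
  }
  comp <- closure(as.matrix(data_used[, parts, drop = FALSE]), total = total)
  sbp <- sbp_pivot(length(parts), pivot)
  z <- ilr(comp, sbp)

  ilr_names <- colnames(z)
  mf <- cbind(data_used[, c(response, covs), drop = FALSE],
              as.data.frame(z))
  full_formula <- stats::reformulate(c(ilr_names, covs), response = response)
  fit <- stats::lm(full_formula, data = mf)

  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(alias, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) stop("fewer rows than design columns")

  structure(list(
    lm = fit,
    formula = formula,
    sbp = sbp,
    pivot = pivot,
    parts = parts,
    total = total,
    covariates = covs,
    response = response,
    ilr_names = ilr_names,
    model_data = data_used,
    comp = comp,
    n_used = nrow(X),
    call = match.call()
  ), class = "coda_lm")
}

#' Fit the staged well-being models 1-3
#'
#' Convenience wrapper fitting the unadjusted, partially adjusted and fully
#' adjusted models (see [model_covariates()]) on one cohort.
#'
#' @param data analysed cohort (see [coda_lm()]).
#' @param models which of 1:3 to fit.
#' @param response outcome column name (default `"wemwbs"`).
#' @param ... passed to [coda_lm()].
#' @return named list `model1`, `model2`, ... of `coda_lm` fits.
#' @export
fit_wellbeing_models <- function(data, models = 1:3, response = "wemwbs",
                                 ...) {
  fits <- lapply(models, function(m) {
    covs <- model_covariates(m)
    f <- stats::reformulate(if (length(covs)) covs else "1",
                            response = response)
    coda_lm(f, data, ...)
  })
  names(fits) <- paste0("model", models)
  fits
}

#' @export
print.coda_lm <- function(x, digits = 3, ...) {
  cat("Compositional linear model (", length(x$parts), "-part, pivot = ",
      x$parts[x$pivot], ")\n", sep = "")
  cat("Outcome:", x$response, "  n =", x$n_used, "\n")
  cat("Covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  cat("Coefficients:\n")
  print(round(stats::coef(x$lm), digits))
  invisible(x)
}

#' @export
coef.coda_lm <- function(object, ...) stats::coef(object$lm)

#' @export
vcov.coda_lm <- function(object, ...) stats::vcov(object$lm)

#' @export
residuals.coda_lm <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.coda_lm <- function(object, ...) stats::fitted(object$lm)

#' @export
confint.coda_lm <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$lm, parm = parm, level = level)
}

#' @export
df.residual.coda_lm <- function(object, ...) stats::df.residual(object$lm)

#' @export
nobs.coda_lm <- function(object, ...) object$n_used

#' Predict from a compositional linear model
#'
#' @param object a `coda_lm` fit.
#' @param newdata data frame with the composition columns and any model
#'   covariates; omitted for in-sample predictions.
#' @param ... passed to [stats::predict.lm()] (e.g. `interval`, `se.fit`).
#' @return predictions as from `predict.lm`.
#' @export
predict.coda_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  newdata <- .prepare_covariates(newdata, object$covariates)
  comp <- closure(as.matrix(newdata[, object$parts, drop = FALSE]),
                  total = object$total)
  z <- ilr(comp, object$sbp)
  nd <- cbind(newdata, as.data.frame(z))
  stats::predict(object$lm, newdata = nd, ...)
}

#' Refit a compositional model under a different pivot
#'
#' Same data, same covariates, same column space -- only the ILR basis is
#' rotated so that a different behaviour occupies the first coordinate.
#'
#' @param object a `coda_lm` fit.
#' @param pivot behaviour name or index for the new first coordinate.
#' @return a new `coda_lm` fit.
#' @export
rotate_pivot <- function(object, pivot) {
  coda_lm(object$formula, object$model_data, pivot = pivot,
          parts = object$parts, total = object$total)
}

# Overall F-test p-value of an lm fit (NA for an intercept-only model).
.model_f_p <- function(fit) {
  fs <- summary(fit)$fstatistic
  if (is.null(fs)) return(NA_real_)
  unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
}

#' Per-behaviour coefficients by pivot rotation
#'
#' For each behaviour, refits the model with that behaviour as the first
#' pivot coordinate and reports its coefficient: the association of time in
#' that behaviour relative to all remaining behaviours, per unit ILR.
#' R-squared and the overall model-fit F-test p-value are invariant to the
#' rotation and reported once per model.
#'
#' @param object a `coda_lm` fit (any pivot).
#' @return data frame with one row per behaviour: `behaviour`, `beta`, `se`,
#'   `t`, `p`, and the shared `r_squared`, `model_p`, `n_used`.
#' @export
behaviour_betas <- function(object) {
  rows <- lapply(seq_along(object$parts), function(p) {
    f <- if (p == object$pivot) object else rotate_pivot(object, p)
    sm <- summary(f$lm)$coefficients
    first <- f$ilr_names[1L]
    data.frame(behaviour = object$parts[p],
               beta = sm[first, "Estimate"],
               se = sm[first, "Std. Error"],
               t = sm[first, "t value"],
               p = sm[first, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$r_squared <- summary(object$lm)$r.squared
  out$model_p <- .model_f_p(object$lm)
  out$n_used <- object$n_used
  rownames(out) <- NULL
  out
}

#' @export
summary.coda_lm <- function(object, ...) {
  structure(list(
    fit = object,
    behaviours = behaviour_betas(object),
    lm_summary = summary(object$lm)
  ), class = "summary.coda_lm")
}

#' @export
print.summary.coda_lm <- function(x, digits = 2, ...) {
  f <- x$fit
  cat("Compositional linear model of", f$response, "on the",
      length(f$parts), "-part day\n")
  cat("n =", f$n_used, " covariates:",
      if (length(f$covariates)) paste(f$covariates, collapse = ", ")
      else "(none)", "\n\n")
  cat("Per-behaviour associations (each behaviour vs all others, per unit",
      "ILR):\n")
  b <- x$behaviours
  tab <- data.frame(behaviour = toupper(b$behaviour),
                    beta = round(b$beta, digits),
                    se = round(b$se, digits),
                    p = signif(b$p, 2))
  print(tab, row.names = FALSE)
  cat("\nR-squared:", round(b$r_squared[1L], 3),
      " overall model p:",
      if (is.na(b$model_p[1L])) "NA" else signif(b$model_p[1L], 2), "\n")
  invisible(x)
}

#' Simulate responses from a fitted compositional model
#'
#' Draws new outcome vectors from the fitted Gaussian model at the analysed
#' design points (parametric bootstrap), via [stats::simulate.lm()].
#'
#' @param object a `coda_lm` fit.
#' @param nsim number of response vectors.
#' @param seed passed to `simulate.lm`.
#' @param ... further arguments to `simulate.lm`.
#' @return data frame of simulated responses.
#' @export
simulate.coda_lm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)
}
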