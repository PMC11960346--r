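# Simplex operations for 4-part (or general D-part) time-use compositions:
# closure, zero handling, geometric-mean composition, variation matrix, and
# isometric log-ratio (ILR) coordinates built from a sequential binary
# partition (SBP) in "pivot" form.

#' Behaviour part names, in canonical order
#'
#' The fixed part order used throughout the package: total sleep time,
#' sedentary behaviour, light physical activity, moderate-to-vigorous
#' physical activity.
#' @export
BEHAVIOURS <- c("tst", "sb", "lpa", "mvpa")

# Relative tolerance for closure / round-trip checks.
.CLOSURE_TOL <- 1e-9

#' Close a composition to a constant total
#'
#' Rescales a positive vector (or the rows of a matrix/data frame) so its
#' parts sum to `total`. Compositions carry only relative information, so
#' closure is the canonical representative on the simplex; here the total is
#' the 1440 minutes of a day.
#'
#' @param x positive numeric vector, or a matrix/data frame with one
#'   composition per row.
#' @param total closure constant, in the units of `x` (default 1440 min).
#' @return object of the same shape as `x`, rows summing to `total`.
#'   Idempotent: `closure(closure(x)) == closure(x)`.
#' @examples
#' closure(c(1, 1, 1, 1))          # 360 360 360 360
#' closure(c(340, 830, 155, 115))  # already sums to 1440: unchanged
#' @export
closure <- function(x, total = 1440) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (any(!is.finite(x))) stop("'x' contains non-finite values")
  if (any(x <= 0)) {
    stop("closure requires strictly positive parts; ",
         "run check_zeros() and, if needed, replace_zeros() first")
  }
  if (is.matrix(x)) {
    sweep(x, 1L, rowSums(x), "/") * total
  } else {
    x * total / sum(x)
  }
}

#' Count zero entries per compositional part
#'
#' Log-ratio methods are undefined at zero. This reports how many zeros each
#' part has so the caller can decide whether to proceed untransformed (no
#' zeros), apply [replace_zeros()], or abort.
#'
#' @param x matrix or data frame of raw part values, one row per participant.
#' @param parts column names holding the parts (default [BEHAVIOURS] if
#'   present, else all columns).
#' @return object of class `"zero_report"`: a named integer vector of zero
#'   counts per part, with attribute `proceed` (`TRUE` iff no zeros).
#' @export
check_zeros <- function(x, parts = NULL) {
  if (is.data.frame(x)) {
    if (is.null(parts)) {
      parts <- if (all(BEHAVIOURS %in% names(x))) BEHAVIOURS else names(x)
    }
    x <- as.matrix(x[, parts, drop = FALSE])
  }
  counts <- if (nrow(x) == 0L) {
    stats::setNames(integer(ncol(x)), colnames(x))
  } else {
    colSums(x == 0)
  }
  storage.mode(counts) <- "integer"
  structure(counts, proceed = all(counts == 0L), class = "zero_report")
}

#' @export
print.zero_report <- function(x, ...) {
  cat("Zero entries per part:\n")
  print(unclass(x)[seq_along(x)])
  if (attr(x, "proceed")) {
    cat("No zero values; no recoding required.\n")
  } else {
    cat("Zeros present: apply replace_zeros() before log-ratio analysis.\n")
  }
  invisible(x)
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts by a small detection-limit value `delta` and rescales
#' the non-zero parts by `1 - k*delta/total` (k = number of zeros) so the
#' row total is preserved.
#'
#' @param x numeric vector, or matrix/data frame of rows, with zeros allowed.
#' @param delta replacement value in the units of `x` (default 1 minute).
#' @param total row total to preserve; defaults to each row's own sum.
#' @return positive vector/matrix with the same totals as the input.
#' @export
replace_zeros <- function(x, delta = 1, total = NULL) {
  if (delta <= 0) stop("'delta' must be positive")
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, replace_zeros, delta = delta, total = total))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (any(x < 0)) stop("parts must be non-negative")
  tot <- if (is.null(total)) sum(x) else total
  k <- sum(x == 0)
  if (k == 0L) return(x)
  if (k * delta >= tot) {
    stop("infeasible delta: ", k, " zeros x delta ", delta,
         " >= total ", tot)
  }
  out <- x * (1 - k * delta / tot)
  out[x == 0] <- delta
  out
}

#' Geometric-mean composition of a sample
#'
#' The part-wise geometric mean across participants, closed to `total`. This
#' is the standard centre of a compositional sample and the default reference
#' composition for isotemporal substitution.
#'
#' @param x matrix or data frame of positive compositions, one row per
#'   participant.
#' @param parts columns holding the parts (data frames only; default
#'   [BEHAVIOURS] if present).
#' @param total closure constant (default 1440 min).
#' @return named numeric vector summing to `total`.
#' @export
comp_gmean <- function(x, parts = NULL, total = 1440) {
  if (is.data.frame(x)) {
    if (is.null(parts)) {
      parts <- if (all(BEHAVIOURS %in% names(x))) BEHAVIOURS else names(x)
    }
    x <- as.matrix(x[, parts, drop = FALSE])
  }
  if (nrow(x) == 0L) stop("empty dataset")
  if (any(x <= 0)) stop("all parts must be strictly positive")
  closure(exp(colMeans(log(x))), total = total)
}

#' Pairwise log-ratio variation matrix
#'
#' Entry (i, j) is the sample variance over participants of
#' `log(x_i / x_j)`. Values near zero indicate strong co-dependence of the
#' two parts; the matrix is symmetric with a zero diagonal and is invariant
#' to closure of the input.
#'
#' @inheritParams comp_gmean
#' @return D x D symmetric matrix with zero diagonal.
#' @export
variation_matrix <- function(x, parts = NULL) {
  if (is.data.frame(x)) {
    if (is.null(parts)) {
      parts <- if (all(BEHAVIOURS %in% names(x))) BEHAVIOURS else names(x)
    }
    x <- as.matrix(x[, parts, drop = FALSE])
  }
  if (nrow(x) < 2L) stop("need at least 2 participants")
  if (any(x <= 0)) stop("all parts must be strictly positive")
  lx <- log(x)
  D <- ncol(x)
  v <- matrix(0, D, D, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(D - 1L)) {
    for (j in (i + 1L):D) {
      v[i, j] <- v[j, i] <- stats::var(lx[, i] - lx[, j])
    }
  }
  v
}

#' Sequential binary partition in pivot form
#'
#' Builds the (D-1) x D sign matrix of the pivot SBP: the first row contrasts
#' the pivot part (+1) against all remaining parts (-1); each subsequent row
#' drops the previous numerator and promotes the next part. `pivot` rotates
#' the part order cyclically before building, so each of the D rotations
#' puts a different part in the first (pivot) coordinate.
#'
#' @param D number of parts.
#' @param pivot index (1..D) of the part placed in the first numerator.
#' @return (D-1) x D integer matrix with entries in `{-1, 0, +1}`.
#' @examples
#' sbp_pivot(4, 1)
#' @export
sbp_pivot <- function(D = 4L, pivot = 1L) {
  D <- as.integer(D)
  pivot <- as.integer(pivot)
  if (D < 2L) stop("'D' must be >= 2")
  if (pivot < 1L || pivot > D) stop("'pivot' must be in 1..", D)
  ord <- ((pivot - 1L + seq_len(D) - 1L) %% D) + 1L  # cyclic rotation
  signs <- matrix(0L, D - 1L, D)
  for (i in seq_len(D - 1L)) {
    signs[i, ord[i]] <- 1L
    signs[i, ord[(i + 1L):D]] <- -1L
  }
  signs
}

#' Orthonormal ILR contrast matrix from an SBP sign matrix
#'
#' Converts a sequential-binary-partition sign matrix into the D x (D-1)
#' contrast (balance) matrix `V` with orthonormal columns, such that
#' `ilr(x) = log(x) %*% V`. Row i of the SBP with r numerator and s
#' denominator parts yields coefficients `+sqrt(s/(r(r+s)))/sqrt(r)`-style
#' weights, i.e. coordinate i equals
#' `sqrt(rs/(r+s)) * log(gmean(num)/gmean(den))`.
#'
#' @param sbp sign matrix as produced by [sbp_pivot()].
#' @return D x (D-1) matrix with orthonormal columns.
#' @export
ilr_basis <- function(sbp) {
  if (!is.matrix(sbp)) stop("'sbp' must be a matrix")
  D <- ncol(sbp)
  V <- matrix(0, D, nrow(sbp))
  for (i in seq_len(nrow(sbp))) {
    num <- sbp[i, ] > 0
    den <- sbp[i, ] < 0
    r <- sum(num); s <- sum(den)
    if (r < 1L || s < 1L) {
      stop("SBP row ", i, " must have at least one +1 and one -1")
    }
    a <- sqrt(r * s / (r + s))
    V[num, i] <- a / r
    V[den, i] <- -a / s
  }
  V
}

#' Isometric log-ratio coordinates
#'
#' Maps positive compositions to (D-1) unconstrained real coordinates using
#' the balance basis of `sbp`. Scale-invariant: `ilr(c * x) == ilr(x)`.
#'
#' @param x positive vector, or matrix/data frame with one composition per
#'   row.
#' @param sbp SBP sign matrix (default: 4-part pivot basis with pivot 1).
#' @return numeric vector of length D-1, or an n x (D-1) matrix, columns
#'   named `ilr1..ilr(D-1)`.
#' @export
ilr <- function(x, sbp = sbp_pivot(4L, 1L)) {
  V <- ilr_basis(sbp)
  if (is.data.frame(x)) x <- as.matrix(x)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(V)) {
    stop("composition has ", ncol(x), " parts but SBP describes ", nrow(V))
  }
  if (any(x <= 0)) stop("ilr requires strictly positive parts")
  z <- log(x) %*% V
  colnames(z) <- paste0("ilr", seq_len(ncol(z)))
  if (vec) drop(z) else z
}

#' Inverse ILR transform
#'
#' Recovers the unique composition (closed to `total`) whose ILR coordinates
#' under `sbp` equal `z`.
#'
#' @param z numeric vector of length D-1, or an n x (D-1) matrix.
#' @param sbp SBP sign matrix used for the forward transform.
#' @param total closure constant (default 1440 min).
#' @return composition vector or matrix, rows summing to `total`.
#' @export
ilr_inv <- function(z, sbp = sbp_pivot(4L, 1L), total = 1440) {
  V <- ilr_basis(sbp)
  vec <- !is.matrix(z)
  if (vec) z <- matrix(z, nrow = 1L)
  if (ncol(z) != ncol(V)) {
    stop("'z' has ", ncol(z), " coordinates but SBP implies ", ncol(V))
  }
  x <- closure(exp(z %*% t(V)), total = total)
  colnames(x) <- rownames(V)
  if (vec) drop(x) else x
}
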