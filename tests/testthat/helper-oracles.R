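# Independent brute-force oracles used to check the implementation paths.

# Non-wear by direct enumeration of admissible intervals: an epoch is
# non-wear iff some interval [a, b] containing it starts and ends on zero
# epochs, has every embedded non-zero run of length <= tol epochs, and
# accumulates >= win epochs of zeros. O(n^2); for small test sequences only.
oracle_nonwear <- function(vm3, win, tol) {
  n <- length(vm3)
  out <- logical(n)
  zero <- vm3 == 0
  for (a in seq_len(n)) {
    if (!zero[a]) next
    zeros <- 0L
    run <- 0L  # current non-zero run length
    for (b in a:n) {
      if (zero[b]) {
        zeros <- zeros + 1L
        run <- 0L
        if (zeros >= win) out[a:b] <- TRUE
      } else {
        run <- run + 1L
        if (run > tol) break
      }
    }
  }
  out
}

# Sleep score by per-epoch recomputation of the weighted window sum, with
# boundary indices clamped (equivalent to repeating the edge epochs).
oracle_sleep <- function(vm3, weights, threshold) {
  n <- length(vm3)
  h <- (length(weights) - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- pmin(pmax(i + (-h):h, 1L), n)
    sum(weights * vm3[idx]) < threshold
  }, logical(1L))
}

# Aitchison distance by the pairwise log-ratio formula.
oracle_aitchison <- function(x, y) {
  D <- length(x)
  s <- 0
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      s <- s + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
    }
  }
  unname(sqrt(s / (2 * D)))
}

# Variation matrix by an explicit pair loop.
oracle_variation <- function(x) {
  D <- ncol(x)
  v <- matrix(0, D, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i != j) v[i, j] <- var(log(x[, i]) - log(x[, j]))
    }
  }
  v
}

# OLS by explicit normal equations.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# A small random positive composition matrix.
random_comps <- function(n, D = 4L, total = 1440) {
  m <- matrix(exp(rnorm(n * D, sd = 0.6)), n, D)
  colnames(m) <- BEHAVIOURS[seq_len(D)]
  closure(m, total = total)
}
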