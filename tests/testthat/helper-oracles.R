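# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths (naive loops, textbook recursions) so that
# agreement is evidence, not tautology.

# Cox-de Boor recursion, written directly from the textbook definition.
# Boundary knots are repeated degree + 1 times; the last interval is closed
# on the right so the basis sums to 1 at the upper endpoint.
deBoorBasis <- function(x, lo, hi, knots, degree) {
  bk <- seq(lo, hi, length.out = knots)
  tv <- c(rep(lo, degree + 1), bk[-c(1, knots)], rep(hi, degree + 1))
  m <- degree + knots - 1
  b0 <- function(i, xx) {
    as.numeric((tv[i] <= xx & xx < tv[i + 1]) |
                 (xx == hi & tv[i] < tv[i + 1] & tv[i + 1] == hi))
  }
  bp <- function(i, p, xx) {
    if (p == 0) return(b0(i, xx))
    d1 <- tv[i + p] - tv[i]
    d2 <- tv[i + p + 1] - tv[i + 1]
    w1 <- if (d1 > 0) (xx - tv[i]) / d1 else 0
    w2 <- if (d2 > 0) (tv[i + p + 1] - xx) / d2 else 0
    w1 * bp(i, p - 1, xx) + w2 * bp(i + 1, p - 1, xx)
  }
  sapply(seq_len(m), function(i) sapply(x, function(xx) bp(i, degree, xx)))
}

# sample skewness / kurtosis (kurtosis as plain fourth standardized moment)
sampleSkew <- function(x) mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
sampleKurt <- function(x) mean((x - mean(x))^4) / (mean((x - mean(x))^2))^2

# naive scalar-loop log-likelihood table
naiveLoglikTable <- function(U, items, points) {
  N <- nrow(U); Q <- length(points)
  out <- matrix(0, N, Q)
  for (i in seq_len(N)) for (q in seq_len(Q)) {
    s <- 0
    for (j in seq_len(ncol(U))) {
      p <- items$c[j] + (1 - items$c[j]) *
        pnorm(items$a[j] * points[q] + items$b[j])
      p <- min(max(p, 1e-12), 1 - 1e-12)
      s <- s + U[i, j] * log(p) + (1 - U[i, j]) * log(1 - p)
    }
    out[i, q] <- s
  }
  out
}

# naive Ramsay-curve evaluation: exponentiate then normalize directly
naiveRamsay <- function(B, eta) {
  u <- exp(as.numeric(B %*% eta))
  u / sum(u)
}

# central finite differences of a scalar function
fdGradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
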