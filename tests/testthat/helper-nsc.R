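# Independent scalar oracle for the shrunken-centroid formulas.

nsc_toy <- function(seed = 1, n = 8, m = 5) {
  set.seed(seed)
  X <- matrix(runif(n * m, 0.1, 0.9), n, m,
              dimnames = list(sprintf("S%d", 1:n), sprintf("cg%d", 1:m)))
  y <- rep(c("no_mild", "severe"), each = n / 2)
  list(X = X, y = y)
}

# re-evaluates every formula with explicit scalar loops
nsc_oracle <- function(X, y, delta) {
  classes <- sort(unique(y))
  n <- nrow(X); m <- ncol(X)
  n_k <- sapply(classes, function(k) sum(y == k))
  xbar <- colMeans(X)
  out <- list(d = matrix(0, 2, m), d_shrunk = matrix(0, 2, m),
              centroids = matrix(0, 2, m, dimnames = list(classes, NULL)))
  s <- numeric(m)
  for (i in 1:m) {
    ss <- 0
    for (k in classes)
      ss <- ss + sum((X[y == k, i] - mean(X[y == k, i]))^2)
    s[i] <- sqrt(ss / (n - 2))
  }
  s0 <- median(s)
  for (ki in 1:2) {
    k <- classes[ki]
    mk <- sqrt(1 / n_k[k] - 1 / n)
    for (i in 1:m) {
      dik <- (mean(X[y == k, i]) - xbar[i]) / (mk * (s[i] + s0))
      dpik <- sign(dik) * max(abs(dik) - delta, 0)
      out$d[ki, i] <- dik
      out$d_shrunk[ki, i] <- dpik
      out$centroids[ki, i] <- xbar[i] + mk * (s[i] + s0) * dpik
    }
  }
  out$s <- s; out$s0 <- s0
  out
}
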