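## Independent brute-force oracles used across the suite.  These deliberately
## avoid the code paths they check.

## Benjamini-Hochberg step-up by direct definition:
## adjusted_(i) = min_{j >= i} (m * p_(j) / j), capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## One-way ANOVA eta-squared by explicit sum-of-squares decomposition.
eta2_bruteforce <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_between / ss_total
}

## Ridge regression closed form with an unpenalized intercept: coefficients
## on centered data, b = (Xc'Xc + n * lambda * I)^-1 Xc'y_c (matches the
## 1/(2n) least-squares + lambda/2 ||b||^2 objective).
ridge_closed_form <- function(X, y, lambda) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  solve(crossprod(Xc) + n * lambda * diag(ncol(X)), crossprod(Xc, yc))
}

## Pure-L1 (lasso) solver by cyclic coordinate descent on the objective
## 1/(2n) ||y - b0 - X b||^2 + lambda ||b||_1, with unpenalized intercept.
lasso_coordinate_descent <- function(X, y, lambda, tol = 1e-12,
                                     maxit = 100000L) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  b <- rep(0, p)
  xss <- colSums(Xc^2) / n
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  r <- yc
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- b[j]
      rho <- sum(Xc[, j] * r) / n + xss[j] * bj_old
      bj <- soft(rho, lambda) / xss[j]
      if (bj != bj_old) {
        r <- r - Xc[, j] * (bj - bj_old)
        delta <- max(delta, abs(bj - bj_old))
      }
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

## Cohen's kappa (unweighted) from first principles on label vectors.
kappa_bruteforce <- function(obs, pred) {
  lev <- sort(unique(c(obs, pred)))
  n <- length(obs)
  po <- mean(obs == pred)
  pe <- sum(vapply(lev, function(l) {
    mean(obs == l) * mean(pred == l)
  }, numeric(1)))
  (po - pe) / (1 - pe)
}
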