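# Independent oracles. These deliberately share no code with the package:
# PLS1 predictions are recomputed from the Krylov-subspace (conjugate
# gradient) characterization, OLS from the normal equations, and LOO-CV by a
# literal loop.

# PLS1 with `a` components regresses y on the Krylov space
# span{X'y, (X'X)X'y, ..., (X'X)^(a-1) X'y}. Orthonormalize the basis for
# numerical stability, then project.
krylov_pls_coef <- function(X, y, a) {
  S <- crossprod(X)
  v <- crossprod(X, y)
  K <- matrix(0, ncol(X), a)
  k <- v
  for (j in seq_len(a)) {
    K[, j] <- k
    k <- S %*% k
  }
  Q <- qr.Q(qr(K))
  drop(Q %*% solve(crossprod(Q, S %*% Q), crossprod(Q, v)))
}

ols_coef <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Brute-force leave-one-out CV: per left-out sample, hand-rolled autoscaling
# on the rest and a Krylov-oracle fit, residuals pooled per model order.
loo_rmsecv_oracle <- function(X, y, lv_grid) {
  n <- nrow(X)
  res <- matrix(NA_real_, n, length(lv_grid))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    mu <- colMeans(Xtr); sds <- apply(Xtr, 2, sd)
    Xs <- sweep(sweep(Xtr, 2, mu, "-"), 2, sds, "/")
    ym <- mean(ytr); ys <- sd(ytr)
    yss <- (ytr - ym) / ys
    xte <- (X[i, ] - mu) / sds
    for (j in seq_along(lv_grid)) {
      b <- krylov_pls_coef(Xs, yss, lv_grid[j])
      res[i, j] <- y[i] - (sum(xte * b) * ys + ym)
    }
  }
  sqrt(colMeans(res^2))
}
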