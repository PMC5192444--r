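# Independent reference computations used as oracles. These deliberately
# avoid the package's own code paths.

# Univariate PLS via its Krylov-subspace characterisation: the A-component
# PLS1 coefficient vector is the least-squares solution of centred y on
# centred X restricted to span{s, (X'X)s, ..., (X'X)^(A-1) s}, s = X'y.
krylov_pls1_predict <- function(X, y, A, X_new) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  s <- drop(crossprod(Xc, yc))
  XtX <- crossprod(Xc)
  K <- matrix(0, ncol(X), A)
  K[, 1L] <- s
  if (A > 1L) for (a in 2:A) K[, a] <- XtX %*% K[, a - 1L]
  Qk <- qr.Q(qr(K))
  Z <- Xc %*% Qk
  gamma <- solve(crossprod(Z), crossprod(Z, yc))
  b <- Qk %*% gamma
  drop(sweep(X_new, 2L, xm) %*% b) + ym
}

# First PLS weight as the dominant eigenvector of Xc' Yc Yc' Xc.
first_weight_eigen <- function(X, Y) {
  Xc <- sweep(X, 2L, colMeans(X)); Yc <- sweep(Y, 2L, colMeans(Y))
  M <- crossprod(Xc, Yc) %*% crossprod(Yc, Xc)
  w <- eigen(M, symmetric = TRUE)$vectors[, 1L]
  w / sqrt(sum(w^2))
}

# Explicit leave-one-out error curve: one full refit per candidate
# component count and held-out sample (no nested-prediction shortcut).
loocv_curve_oracle <- function(X, Y, scheme, max_lv) {
  n <- nrow(X)
  truth <- as.matrix(crisp(Y, scheme))
  err <- integer(max_lv)
  for (a in seq_len(max_lv)) {
    for (i in seq_len(n)) {
      m <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                   min(a, n - 2L, ncol(X)))
      pred <- crisp(drop(predict(m, X[i, , drop = FALSE],
                                 min(a, m$n_components))), scheme)
      err[a] <- err[a] + block_errors(pred, truth[i, ])
    }
  }
  err
}

# Mean silhouette width over a labelled distance structure, from scratch.
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(D[i, labels == l]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
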