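# Independent oracles used to cross-check the package implementation.
# These are written directly from textbook formulations and share no code
# with the package internals.

# Literal transcription of de Jong's SIMPLS pseudocode. The weight vector is
# obtained via the dominant eigenvector of t(S) %*% S (a different numerical
# route than the package's SVD of S).
simpls_oracle <- function(X, Y, A) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  X0 <- sweep(X, 2, x_mean); Y0 <- sweep(Y, 2, y_mean)
  S <- t(X0) %*% Y0
  R <- matrix(0, p, A); Q <- matrix(0, m, A); V <- matrix(0, p, A)
  for (a in seq_len(A)) {
    q <- eigen(t(S) %*% S, symmetric = TRUE)$vectors[, 1]
    r <- S %*% q
    t_ <- X0 %*% r
    t_ <- t_ - mean(t_)
    normt <- sqrt(sum(t_^2))
    t_ <- t_ / normt
    r <- r / normt
    p_ <- t(X0) %*% t_
    q_ <- t(Y0) %*% t_
    v <- p_
    if (a > 1) {
      Vprev <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vprev %*% (t(Vprev) %*% p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% (t(v) %*% S)
    R[, a] <- r; Q[, a] <- q_; V[, a] <- v
  }
  B <- R %*% t(Q)
  function(Xnew) {
    sweep(sweep(as.matrix(Xnew), 2, x_mean) %*% B, 2, y_mean, "+")
  }
}

# Classical NIPALS PLS1 for a univariate response, with X-deflation.
nipals_pls1_oracle <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xa <- sweep(X, 2, x_mean); ya <- y - y_mean
  W <- NULL; P <- NULL; q <- numeric(0)
  for (a in seq_len(A)) {
    w <- t(Xa) %*% ya
    w <- w / sqrt(sum(w^2))
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    p_ <- t(Xa) %*% t_ / tt
    qa <- sum(ya * t_) / tt
    Xa <- Xa - t_ %*% t(p_)
    ya <- ya - qa * t_
    W <- cbind(W, w); P <- cbind(P, p_); q <- c(q, qa)
  }
  B <- W %*% solve(t(P) %*% W, q)
  function(Xnew) {
    y_mean + sweep(as.matrix(Xnew), 2, x_mean) %*% B
  }
}

# Minimum-norm ordinary least squares on centered data via the SVD
# pseudoinverse; the PLS solution at n_factors = rank must coincide.
minnorm_ols_oracle <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  X0 <- sweep(X, 2, x_mean); Y0 <- sweep(Y, 2, y_mean)
  sv <- svd(X0)
  pos <- sv$d > max(sv$d) * 1e-10
  B <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) %*% Y0 / sv$d[pos])
  function(Xnew) {
    sweep(sweep(as.matrix(Xnew), 2, x_mean) %*% B, 2, y_mean, "+")
  }
}

# Naive loop-based residual statistics.
metrics_oracle <- function(y_true, y_hat) {
  r <- c()
  yt <- as.matrix(y_true); yh <- as.matrix(y_hat)
  for (j in seq_len(ncol(yt))) {
    for (i in seq_len(nrow(yt))) {
      r <- c(r, yh[i, j] - yt[i, j])
    }
  }
  n <- length(r)
  ss <- 0
  for (v in r) ss <- ss + v^2
  mu <- sum(r) / n
  list(
    press = ss,
    rmse = sqrt(ss / n),
    bias = mu,
    std = sqrt(sum((r - mu)^2) / (n - 1))
  )
}
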