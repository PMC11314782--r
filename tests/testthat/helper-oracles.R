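# Independent brute-force oracles used to freeze expected values.
# These deliberately use naive loops / alternative formulations so they
# share no code path with the package implementation.

# windowed-mean resampling: explicit loop over output bands
oracle_window_mean <- function(wl, x, interval) {
  new_wl <- seq(wl[1], wl[length(wl)], by = interval)
  sapply(new_wl, function(w) {
    inside <- wl >= w - interval / 2 & wl < w + interval / 2
    mean(x[inside])
  })
}

# Savitzky-Golay by explicit per-window polynomial least squares,
# with edge values taken from the polynomial of the nearest full window
oracle_savgol <- function(x, window, order) {
  m <- length(x)
  half <- (window - 1) / 2
  out <- numeric(m)
  for (i in seq_len(m)) {
    c0 <- min(max(i, half + 1), m - half)  # centre of nearest full window
    idx <- (c0 - half):(c0 + half)
    fit <- stats::lm(y ~ poly(t, order, raw = TRUE),
                     data = data.frame(t = idx - c0, y = x[idx]))
    out[i] <- unname(stats::predict(fit, data.frame(t = i - c0)))
  }
  out
}

# weighted covariance: explicit double loop over matrix entries
oracle_weighted_cov <- function(X, w) {
  wn <- w / sum(w)
  mu <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) mu[j] <- sum(wn * X[, j])
  S <- matrix(0, ncol(X), ncol(X))
  for (a in seq_len(ncol(X)))
    for (b in seq_len(ncol(X)))
      S[a, b] <- sum(wn * (X[, a] - mu[a]) * (X[, b] - mu[b]))
  S
}

# eigenvalues of a symmetric 3x3 matrix via the characteristic polynomial
oracle_eigvals_3x3 <- function(S) {
  stopifnot(nrow(S) == 3)
  c2 <- -sum(diag(S))
  c1 <- S[1, 1] * S[2, 2] + S[1, 1] * S[3, 3] + S[2, 2] * S[3, 3] -
    S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2
  c0 <- -det(S)
  r <- polyroot(c(c0, c1, c2, 1))
  sort(Re(r), decreasing = TRUE)
}

# Kennard-Stone greedy selection, naive O(n^3)
oracle_ks <- function(X, n_cal) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  pair <- c(1, 2); best <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > best) { best <- D[i, j]; pair <- c(i, j) }
  sel <- pair
  while (length(sel) < n_cal) {
    cand_best <- -1; cand <- NA
    for (j in setdiff(seq_len(n), sel)) {
      dmin <- min(D[j, sel])
      if (dmin > cand_best) { cand_best <- dmin; cand <- j }
    }
    sel <- c(sel, cand)
  }
  sel
}

# PLS regression coefficients via the Krylov-subspace characterization:
# the a-component PLS solution minimizes RSS over span{s, Cs, ..., C^(a-1)s},
# s = X'y, C = X'X (centred). Independent of the NIPALS recursion.
oracle_pls_coef <- function(X, y, a) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  C <- crossprod(Xc)
  K <- matrix(0, ncol(X), a)
  v <- s
  for (h in seq_len(a)) { K[, h] <- v; v <- C %*% v }
  Q <- qr.Q(qr(K))
  beta <- Q %*% solve(crossprod(Q, C %*% Q), crossprod(Q, s))
  list(beta = as.numeric(beta),
       intercept = mean(y) - sum(colMeans(X) * beta))
}

# textbook NIPALS, written as the classic deflation loop
oracle_nipals_coef <- function(X, y, a) {
  E <- sweep(X, 2, colMeans(X)); f <- y - mean(y)
  W <- NULL; P <- NULL; q <- c()
  for (h in seq_len(a)) {
    w <- t(E) %*% f
    w <- w / sqrt(sum(w^2))
    t_ <- E %*% w
    p <- t(E) %*% t_ / sum(t_^2)
    qh <- sum(f * t_) / sum(t_^2)
    E <- E - t_ %*% t(p)
    f <- f - t_ * qh
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qh)
  }
  beta <- W %*% solve(t(P) %*% W) %*% q
  list(beta = as.numeric(beta),
       intercept = mean(y) - sum(colMeans(X) * beta))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small fast scene for unit tests
small_scene <- function(n = 40, seed = 3, ...) {
  generate_scene(scene_config(n_per_cluster = n, ...), seed = seed)
}

# standard preprocessing used across tests
preprocess <- function(ds) savgol_smooth(to_absorbance(ds))
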