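#' Fuzzy c-means clustering
#'
#' Bezdek alternating optimization of J = sum_i sum_j u_ij^m d_ij^2 with
#' squared Euclidean distances and column-stochastic memberships
#' (sum_i u_ij = 1 for every sample j). Given memberships the centers are
#' the membership-weighted means; given centers the memberships follow the
#' closed-form update u_ij = \[sum_l (d_ij/d_lj)^(2/(m-1))\]^-1. Iteration
#' stops when the largest absolute membership change falls below `tol` or
#' after `max_iter` iterations. The best of `restarts` seeded starts (by
#' final J) is returned.
#'
#' Initialization places the centers on per-dimension quantile anchors with
#' seeded jitter; the start therefore depends only on the data values and
#' the seed, not on the row order, so permuting the samples permutes the
#' membership columns identically.
#'
#' A sample coincident with one or more centers splits its membership
#' equally among the coincident centers.
#'
#' @param Z n x k score matrix (rows = samples).
#' @param c number of clusters, `1 <= c <= n`.
#' @param fuzziness fuzzy weighting exponent m > 1 (default 1.5).
#' @param max_iter maximum iterations (default 300).
#' @param tol convergence threshold on max |delta U| (default 0.001).
#' @param seed integer seed for the restart schedule.
#' @param restarts number of random initializations (default 5).
#' @return an object of class `fcm_result`: `U` (c x n memberships),
#'   `centers` (c x k), `labels` (argmax memberships), `objective`
#'   (J trace of the winning run), `fpi`, `nce`, `iterations`, `seed`.
#' @export
fcm_fit <- function(Z, c, fuzziness = 1.5, max_iter = 300, tol = 1e-3,
                    seed = 1, restarts = 5) {
  Z <- as.matrix(Z)
  n <- nrow(Z); k <- ncol(Z)
  if (c < 1) stop("c must be >= 1")
  if (c > n) stop("c (", c, ") exceeds the number of samples (", n, ")")
  if (fuzziness <= 1) stop("fuzziness must be > 1")
  if (c == 1) {
    U <- matrix(1, 1, n)
    centers <- matrix(colMeans(Z), 1, k)
    J <- sum(sweep(Z, 2, centers[1, ])^2)
    return(structure(list(U = U, centers = centers, labels = rep(1L, n),
                          objective = J, fpi = NA_real_, nce = NA_real_,
                          iterations = 0L, seed = seed, c = 1L),
                     class = "fcm_result"))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- fcm_single_run(Z, c, fuzziness, max_iter, tol, seed + r - 1L)
    if (is.null(best) || utils::tail(run$objective, 1) < utils::tail(best$objective, 1))
      best <- run
  }
  U <- best$U
  out <- structure(list(U = U, centers = best$centers,
                        labels = apply(U, 2, which.max),
                        objective = best$objective,
                        fpi = fpi(U), nce = if (n > c) nce(U) else NA_real_,
                        iterations = best$iterations, seed = seed, c = as.integer(c)),
                   class = "fcm_result")
  out
}

# one seeded FCM run
fcm_single_run <- function(Z, c, m, max_iter, tol, seed) {
  n <- nrow(Z); k <- ncol(Z)
  withr_seed <- function(expr) { # local RNG scope without extra deps
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
  }
  centers <- withr_seed({
    probs <- (seq_len(c) - 0.5) / c
    anchors <- apply(Z, 2, stats::quantile, probs = probs, names = FALSE)
    anchors <- matrix(anchors, nrow = c)
    jit <- matrix(stats::rnorm(c * k), c, k) *
      rep(apply(Z, 2, stats::sd) * 0.3 + 1e-12, each = c)
    anchors + jit
  })
  U <- fcm_memberships(Z, centers, m)
  J_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Um <- U^m
    centers <- (Um %*% Z) / rowSums(Um)
    Unew <- fcm_memberships(Z, centers, m)
    J_trace <- c(J_trace, fcm_objective(Z, centers, Unew, m))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < tol || iter >= max_iter) break
  }
  list(U = U, centers = centers, objective = J_trace, iterations = iter)
}

# squared Euclidean distances centers (c x k) -> samples (n x k): c x n
fcm_dist2 <- function(Z, centers) {
  d2 <- outer(rowSums(centers^2), rowSums(Z^2), "+") - 2 * tcrossprod(centers, Z)
  d2[d2 < 0] <- 0
  d2
}

fcm_memberships <- function(Z, centers, m) {
  d2 <- fcm_dist2(Z, centers)
  expo <- 1 / (m - 1)          # applied to squared distances
  inv <- d2^(-expo)
  U <- sweep(inv, 2, colSums(inv), "/")
  zero <- d2 <= .Machine$double.eps * 100
  coincident <- colSums(zero) > 0
  if (any(coincident)) {
    for (j in which(coincident)) {
      U[, j] <- 0
      U[zero[, j], j] <- 1 / sum(zero[, j])
    }
  }
  U
}

fcm_objective <- function(Z, centers, U, m) {
  sum(U^m * fcm_dist2(Z, centers))
}

#' @export
print.fcm_result <- function(x, ...) {
  cat("<fcm_result> c=", x$c, ", n=", ncol(x$U),
      ", J=", signif(utils::tail(x$objective, 1), 6),
      ", FPI=", signif(x$fpi, 4), ", NCE=", signif(x$nce, 4),
      " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Fuzzy performance index
#'
#' FPI = c (1 - PC) / (c - 1) with the partition coefficient
#' PC = (1/n) sum_ij u_ij^2. Ranges over \[0, 1\]: 0 for a crisp partition
#' (clusters share no samples), 1 for the uniform membership matrix.
#'
#' @param U c x n column-stochastic membership matrix, c >= 2.
#' @return FPI in \[0, 1\].
#' @export
fpi <- function(U) {
  c <- nrow(U); n <- ncol(U)
  if (c < 2) stop("FPI is undefined for c = 1")
  check_memberships(U)
  pc <- sum(U^2) / n
  c * (1 - pc) / (c - 1)
}

#' Normalized classification entropy
#'
#' NCE = n / (n - c) * H with the partition entropy
#' H = -(1/n) sum_ij u_ij log(u_ij) (0 log 0 := 0). Natural log by
#' default; `base` selects another logarithm base. 0 for a crisp
#' partition; larger values mean fuzzier partitions.
#'
#' @param U c x n column-stochastic membership matrix; requires n > c.
#' @param base logarithm base (default `exp(1)`).
#' @return NCE >= 0.
#' @export
nce <- function(U, base = exp(1)) {
  c <- nrow(U); n <- ncol(U)
  if (n <= c) stop("NCE requires n > c")
  check_memberships(U)
  lu <- ifelse(U > 0, log(U, base = base), 0)
  H <- -sum(U * lu) / n
  n / (n - c) * H
}

check_memberships <- function(U) {
  if (any(U < -1e-9) || any(U > 1 + 1e-9))
    stop("memberships must lie in [0, 1]")
  if (any(abs(colSums(U) - 1) > 1e-6))
    stop("membership columns must sum to 1")
  invisible(U)
}

#' Sweep the number of clusters and pick c by validity indices
#'
#' Fits FCM for each candidate c with a shared seed schedule, records FPI
#' and NCE, and chooses the c minimizing the rank-sum of the two indices
#' (ties resolved toward the smaller c). The automatic choice can be
#' overridden downstream; subject-matter matching of the clusters (e.g.
#' against land-cover classes) is deliberately not encoded.
#'
#' @param Z n x k score matrix.
#' @param c_range candidate cluster counts (default 2:10).
#' @param fuzziness,max_iter,tol,seed,restarts passed to [fcm_fit()].
#' @return an object of class `validity_curve`: data frame `curve` with
#'   columns c, fpi, nce; `chosen_c`; the per-c `fits`.
#' @export
sweep_clusters <- function(Z, c_range = 2:10, fuzziness = 1.5,
                           max_iter = 300, tol = 1e-3, seed = 1,
                           restarts = 5) {
  Z <- as.matrix(Z)
  if (max(c_range) >= nrow(Z)) stop("max(c_range) must be < n")
  if (any(c_range < 2)) stop("validity indices need c >= 2")
  fits <- lapply(c_range, function(cc)
    fcm_fit(Z, cc, fuzziness = fuzziness, max_iter = max_iter, tol = tol,
            seed = seed + 1000L * cc, restarts = restarts))
  fpi_v <- vapply(fits, function(f) f$fpi, numeric(1))
  nce_v <- vapply(fits, function(f) f$nce, numeric(1))
  if (all(fpi_v > 0.999))
    warning("all candidate partitions are maximally fuzzy; input may be degenerate")
  rank_sum <- rank(fpi_v, ties.method = "min") + rank(nce_v, ties.method = "min")
  chosen <- c_range[which.min(rank_sum)]
  structure(list(
    curve = data.frame(c = c_range, fpi = fpi_v, nce = nce_v,
                       rank_sum = rank_sum),
    chosen_c = chosen,
    fits = stats::setNames(fits, paste0("c", c_range))
  ), class = "validity_curve")
}

#' @export
print.validity_curve <- function(x, ...) {
  print(x$curve, row.names = FALSE)
  cat("chosen c =", x$chosen_c, "\n")
  invisible(x)
}
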