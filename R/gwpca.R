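#' Bisquare kernel weight
#'
#' w = (1 - (d/b)^2)^2 for d < b, 0 otherwise. The kernel has compact
#' support, so samples beyond the bandwidth carry no weight.
#'
#' @param d non-negative distance(s), same units as `b`.
#' @param b bandwidth, > 0.
#' @return weight(s) in \[0, 1\].
#' @export
bisquare_weight <- function(d, b) {
  if (any(b <= 0)) stop("bandwidth must be > 0")
  if (any(d < 0)) stop("distances must be >= 0")
  w <- (1 - (d / b)^2)^2
  w[d >= b] <- 0
  w
}

#' Kernel specification for GWPCA
#'
#' @param bandwidth fixed bandwidth (km for haversine, coordinate units for
#'   euclidean) or, when `adaptive = TRUE`, the neighbour count.
#' @param metric `"haversine"` (great-circle km on WGS84 lon/lat) or
#'   `"euclidean"` (coordinates taken as planar).
#' @param adaptive logical; adaptive bandwidth = distance to the
#'   `bandwidth`-th nearest neighbour at each location.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(bandwidth, metric = c("haversine", "euclidean"),
                        adaptive = FALSE) {
  metric <- match.arg(metric)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (adaptive && bandwidth != round(bandwidth))
    stop("adaptive bandwidth must be an integer neighbour count")
  structure(list(name = "bisquare", bandwidth = bandwidth, metric = metric,
                 adaptive = adaptive), class = "kernel_spec")
}

#' Pairwise geographic distance matrix
#'
#' @param coords n x 2 matrix of (lon, lat) (haversine) or planar (x, y).
#' @param metric `"haversine"` (km) or `"euclidean"`.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
geo_distances <- function(coords, metric = c("haversine", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    as.matrix(stats::dist(coords))
  } else {
    n <- nrow(coords)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      # distHaversine is vectorized over the second argument; km
      D[i, ] <- geosphere::distHaversine(coords[i, , drop = FALSE], coords) / 1000
    }
    (D + t(D)) / 2  # enforce exact symmetry
  }
}

#' Geographically weighted covariance at one location
#'
#' Sigma(u,v) = (X - mu_w)' diag(w / sum(w)) (X - mu_w) with mu_w the
#' weighted column mean. Normalizing the weights to sum 1 fixes the
#' eigenvalue scale (population convention); eigenvectors are unaffected.
#'
#' @param X n x m matrix (standardized spectra).
#' @param w non-negative weights, length n, sum > 0.
#' @return symmetric positive semi-definite m x m matrix.
#' @export
local_covariance <- function(X, w) {
  if (length(w) != nrow(X)) stop("length(w) != nrow(X)")
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0)
    stop("all weights are zero: bandwidth too small at this location")
  wn <- w / sw
  mu <- colSums(X * wn)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * sqrt(wn))
  (S + t(S)) / 2
}

#' Leading eigenpairs of a symmetric matrix
#'
#' @param S symmetric m x m matrix.
#' @param k number of leading components, `1 <= k <= m`.
#' @return list with `loadings` (m x k, unit-norm columns) and `values`
#'   (length k, descending).
#' @export
local_eigen <- function(S, k) {
  m <- ncol(S)
  if (k > m) stop("k (", k, ") exceeds matrix dimension (", m, ")")
  if (k < 1) stop("k must be >= 1")
  e <- eigen(S, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  vals[vals < 0 & vals > -1e-12] <- 0  # clip PSD round-off
  list(loadings = e$vectors[, seq_len(k), drop = FALSE], values = vals)
}

# Global (unweighted) PCA with the same population-covariance convention
# used throughout GWPCA; reference for sign alignment and limit checks.
global_pca <- function(Xstd, k) {
  S <- local_covariance(Xstd, rep(1, nrow(Xstd)))
  local_eigen(S, k)
}

# z-score each band; zero-variance bands are centred only
standardize_bands <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Number of components to retain
#'
#' Counts the global PCA eigenvalues greater than one on the standardized
#' spectra (Kaiser rule); at least one component is always retained. A
#' single shared k keeps local scores comparable across locations.
#'
#' @param Xstd standardized n x m matrix.
#' @return integer k >= 1.
#' @export
choose_n_components <- function(Xstd) {
  vals <- local_eigen(local_covariance(Xstd, rep(1, nrow(Xstd))),
                      ncol(Xstd))$values
  max(1L, sum(vals > 1))
}

# bandwidth -> per-location weight rows; adaptive converts the neighbour
# count into a local fixed bandwidth (distance to the bw-th neighbour)
kernel_weights <- function(D, kernel) {
  n <- nrow(D)
  if (kernel$adaptive) {
    nb <- kernel$bandwidth
    if (nb < 2 || nb > n) stop("adaptive neighbour count out of range")
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      bi <- sort(D[i, ])[nb]
      if (bi <= 0) stop("degenerate geometry: coincident points exhaust the neighbour count")
      # include the nb-th neighbour itself with small positive weight
      W[i, ] <- bisquare_weight(D[i, ], bi * (1 + 1e-9))
    }
    W
  } else {
    t(apply(D, 1, bisquare_weight, b = kernel$bandwidth))
  }
}

#' Leave-one-out reconstruction score of a candidate bandwidth
#'
#' For every sample i, local loadings are fitted at i's location with i
#' held out, and the score accumulates the squared residual of projecting
#' x_i onto that local k-dimensional basis. Small bandwidths that leave a
#' location without support score `Inf`.
#'
#' @param Xstd standardized matrix; `D` pairwise distances; `k` components;
#'   `bandwidth` candidate; `adaptive` logical.
#' @return non-negative score (sum of squared reconstruction residuals).
#' @export
gwpca_loo_score <- function(Xstd, D, k, bandwidth, adaptive = FALSE) {
  n <- nrow(Xstd)
  total <- 0
  for (i in seq_len(n)) {
    d <- D[i, -i]
    if (adaptive) {
      bi <- sort(d)[min(bandwidth, n - 1)] * (1 + 1e-9)
      w <- bisquare_weight(d, bi)
    } else {
      w <- bisquare_weight(d, bandwidth)
    }
    if (sum(w > 0) < k + 1) return(Inf)
    Xo <- Xstd[-i, , drop = FALSE]
    S <- local_covariance(Xo, w)
    L <- local_eigen(S, k)$loadings
    mu <- colSums(Xo * (w / sum(w)))
    xc <- Xstd[i, ] - mu
    r <- xc - L %*% crossprod(L, xc)
    total <- total + sum(r^2)
  }
  total
}

#' Select a GWPCA bandwidth
#'
#' Minimizes the leave-one-out reconstruction score. Fixed bandwidths are
#' searched by golden section over \[smallest non-zero distance, largest
#' distance\]; adaptive bandwidths by integer search over the neighbour
#' counts.
#'
#' @param Xstd standardized n x m matrix.
#' @param coords n x 2 coordinates.
#' @param k retained components.
#' @param metric distance metric, see [geo_distances()].
#' @param adaptive logical; select a neighbour count instead of a distance.
#' @param tol relative golden-section tolerance.
#' @return a [kernel_spec()] with the selected bandwidth.
#' @export
select_bandwidth <- function(Xstd, coords, k,
                             metric = c("haversine", "euclidean"),
                             adaptive = FALSE, tol = 0.01) {
  metric <- match.arg(metric)
  n <- nrow(Xstd)
  if (n < k + 2) stop("need at least k + 2 samples to select a bandwidth")
  D <- geo_distances(coords, metric)
  pos <- D[upper.tri(D)]
  if (all(pos == 0)) stop("degenerate geometry: all points coincident")
  if (adaptive) {
    lo <- max(k + 2, 3)
    cand <- unique(round(seq(lo, n - 1, length.out = min(20, n - lo))))
    scores <- vapply(cand, function(nb)
      gwpca_loo_score(Xstd, D, k, nb, adaptive = TRUE), numeric(1))
    return(kernel_spec(cand[which.min(scores)], metric, adaptive = TRUE))
  }
  lo <- min(pos[pos > 0])
  hi <- max(pos)
  f <- function(b) gwpca_loo_score(Xstd, D, k, b, adaptive = FALSE)
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol * hi) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  best <- if (f1 <= f2) x1 else x2
  # guard against an infeasible (Inf-scoring) golden-section endpoint
  if (!is.finite(f(best))) best <- hi
  kernel_spec(best, metric, adaptive = FALSE)
}

#' Fit geographically weighted PCA
#'
#' At each sample location a bisquare-weighted covariance of the (globally
#' standardized) spectra is decomposed; the sample is scored by projecting
#' its globally standardized spectrum onto its own local loadings
#' (Z_i = x_i,std L_i). The projection is deliberately not re-centred on
#' the local weighted mean: that would remove the between-region mean
#' structure the downstream clustering is meant to find.
#' Local eigenvector columns are sign-aligned to the global
#' PCA loadings (flip when the dot product is negative) so that scores are
#' comparable across locations — a requirement for clustering them.
#'
#' @param ds a `spectral_dataset` (preprocessed; standardization is
#'   internal).
#' @param k number of components; `"auto"` uses [choose_n_components()].
#' @param kernel a [kernel_spec()]; `NULL` selects a fixed bandwidth via
#'   [select_bandwidth()].
#' @return an object of class `gwpca_result` with fields `scores` (n x k),
#'   `eigenvalues` (n x k, rows non-increasing), `loadings` (m x k x n
#'   array), `global_loadings`, `global_values`, `k`, `kernel`.
#' @export
fit_gwpca <- function(ds, k = "auto", kernel = NULL) {
  X <- ds$values
  Xstd <- standardize_bands(X)
  if (identical(k, "auto")) k <- choose_n_components(Xstd)
  k <- as.integer(k)
  n <- nrow(Xstd); m <- ncol(Xstd)
  if (k < 1 || k > m) stop("k out of range")
  if (is.null(kernel))
    kernel <- select_bandwidth(Xstd, ds$coords, k)
  D <- geo_distances(ds$coords, kernel$metric)
  W <- kernel_weights(D, kernel)
  g <- global_pca(Xstd, k)
  scores <- matrix(NA_real_, n, k)
  eigenvalues <- matrix(NA_real_, n, k)
  loadings <- array(NA_real_, dim = c(m, k, n))
  for (i in seq_len(n)) {
    w <- W[i, ]
    nz <- which(w > 0)
    if (length(nz) < k + 1)
      stop("effective sample size ", length(nz), " < k + 1 at sample ",
           ds$ids[i], "; increase the bandwidth")
    S <- local_covariance(Xstd[nz, , drop = FALSE], w[nz])
    e <- local_eigen(S, k)
    L <- e$loadings
    flip <- colSums(L * g$loadings) < 0
    L[, flip] <- -L[, flip]
    scores[i, ] <- as.numeric(Xstd[i, ] %*% L)
    eigenvalues[i, ] <- e$values
    loadings[, , i] <- L
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 loadings = loadings, global_loadings = g$loadings,
                 global_values = g$values, k = k, kernel = kernel,
                 ids = ds$ids),
            class = "gwpca_result")
}

#' @export
print.gwpca_result <- function(x, ...) {
  cat("<gwpca_result> ", length(x$ids), " samples, k=", x$k,
      ", bisquare ", if (x$kernel$adaptive) "adaptive " else "fixed ",
      "bandwidth=", signif(x$kernel$bandwidth, 5),
      " (", x$kernel$metric, ")\n", sep = "")
  invisible(x)
}
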