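test_that("bisquare kernel follows (1 - (d/b)^2)^2 with compact support", {
  expect_equal(bisquare_weight(0, 5), 1)
  expect_equal(bisquare_weight(5, 5), 0)
  expect_equal(bisquare_weight(2.5, 5), 0.5625)
  expect_equal(bisquare_weight(7, 5), 0)
  expect_error(bisquare_weight(1, 0), "bandwidth")
})

test_that("haversine distances are symmetric, zero iff coincident, and plausible", {
  coords <- cbind(lon = c(0, 0, 1, 0), lat = c(0, 0, 0, 1))
  D <- geo_distances(coords, "haversine")
  expect_equal(D, t(D))
  expect_equal(D[1, 2], 0)
  expect_true(all(D[1, 3:4] > 0))
  # one degree is ~111 km at the equator
  expect_equal(D[1, 3], 111.2, tolerance = 0.01)
  expect_equal(D[1, 4], 111.2, tolerance = 0.01)
})

test_that("local covariance reduces to population covariance under uniform weights", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  S <- local_covariance(X, rep(1, 20))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(S, crossprod(Xc) / 20, tolerance = 1e-12)
  # all mass on one sample: no spread
  w1 <- c(1, rep(0, 19))
  expect_equal(local_covariance(X, w1), matrix(0, 3, 3), tolerance = 1e-12)
  expect_error(local_covariance(X, rep(0, 20)), "zero")
})

test_that("local covariance matches the double-loop oracle", {
  set.seed(2)
  for (i in 1:25) {
    X <- matrix(rnorm(18), 6, 3)
    w <- runif(6)
    expect_equal(local_covariance(X, w), oracle_weighted_cov(X, w),
                 tolerance = 1e-12)
  }
})

test_that("local eigen returns descending eigenpairs that reconstruct the input", {
  e <- local_eigen(diag(c(3, 1, 0.5)), 3)
  expect_equal(e$values, c(3, 1, 0.5))
  e2 <- local_eigen(matrix(c(2, 1, 1, 2), 2), 2)
  expect_equal(e2$values, c(3, 1))
  set.seed(3)
  A <- crossprod(matrix(rnorm(25), 5, 5))
  ef <- local_eigen(A, 5)
  expect_equal(ef$loadings %*% diag(ef$values) %*% t(ef$loadings), A,
               tolerance = 1e-8)
  expect_error(local_eigen(A, 6), "exceeds")
})

test_that("eigenvalues agree with the characteristic-polynomial oracle at m = 3", {
  set.seed(4)
  for (i in 1:20) {
    S <- crossprod(matrix(rnorm(15), 5, 3))
    expect_equal(local_eigen(S, 3)$values, oracle_eigvals_3x3(S),
                 tolerance = 1e-8)
  }
})

test_that("component count follows the eigenvalue-greater-than-one rule with floor 1", {
  # three perfectly correlated standardized bands: eigenvalues (3, 0, 0)
  set.seed(5)
  z <- rnorm(200)
  X3 <- scale(cbind(z, 2 * z, -z))
  expect_equal(choose_n_components(X3), 1)
  # independent bands at large n: matches a direct eigen count
  Xi <- scale(matrix(rnorm(500 * 6), 500, 6))
  ev <- eigen(crossprod(Xi) / 500, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(choose_n_components(Xi), max(1, sum(ev > 1)))
  expect_equal(choose_n_components(scale(matrix(rnorm(50), 50, 1))), 1)
})

test_that("GWPCA at huge bandwidth reproduces global PCA eigenstructure and scores", {
  sc <- small_scene(20)
  pp <- preprocess(sc$dataset)
  gw <- fit_gwpca(pp, k = 3, kernel = kernel_spec(1e9, "haversine"))
  Xstd <- scale(pp$values)
  S <- crossprod(sweep(Xstd, 2, colMeans(Xstd))) / nrow(Xstd)
  e <- eigen(S, symmetric = TRUE)
  for (i in seq_len(nrow(gw$eigenvalues)))
    expect_equal(gw$eigenvalues[i, ], e$values[1:3], tolerance = 1e-6)
  L <- e$vectors[, 1:3]
  L <- sweep(L, 2, sign(colSums(L * gw$global_loadings)), "*")
  expect_equal(unname(gw$scores), unname(Xstd %*% L), tolerance = 1e-6)
})

test_that("local eigenvalue rows are sorted and sum to the local covariance trace", {
  # few-band dataset so that k = m is feasible at modest n
  set.seed(6)
  n <- 60
  coords <- cbind(runif(n, 0, 5), runif(n, 40, 45))
  X <- matrix(runif(n * 4, 0.2, 0.8), n, 4)
  ds <- spectral_dataset(paste0("s", 1:n), coords, c(500, 600, 700, 800), X)
  pp <- to_absorbance(ds)
  gw <- fit_gwpca(pp, k = 4, kernel = kernel_spec(600, "haversine"))
  expect_true(all(apply(gw$eigenvalues, 1, function(r) all(diff(r) <= 1e-10))))
  Xstd <- scale(pp$values)
  D <- geo_distances(pp$coords, "haversine")
  for (i in seq_len(n)) {
    w <- bisquare_weight(D[i, ], 600)
    tr <- sum(diag(local_covariance(Xstd[w > 0, , drop = FALSE], w[w > 0])))
    expect_equal(sum(gw$eigenvalues[i, ]), tr, tolerance = 1e-8)
  }
})

test_that("sign alignment makes scores continuous across coincident locations", {
  sc <- small_scene(15)
  ds <- sc$dataset
  # duplicate sample 1 at an essentially identical location
  n <- n_samples(ds)
  ds2 <- spectral_dataset(c(ds$ids, "dup"),
                          rbind(ds$coords, ds$coords[1, ] + 1e-9),
                          ds$wavelengths,
                          rbind(ds$values, ds$values[1, ]),
                          target = c(ds$target, ds$target[1]),
                          mode = "reflectance")
  pp <- preprocess(ds2)
  gw <- fit_gwpca(pp, k = 3, kernel = kernel_spec(600, "haversine"))
  expect_lt(max(abs(gw$scores[1, ] - gw$scores[n + 1, ])), 1e-6)
})

test_that("planted two-region scene yields locally adapted loadings", {
  # two spatially distant regions with different covariance structure:
  # region A varies along band 1, region B along band 2
  set.seed(8)
  nA <- 40; nB <- 40
  wl <- c(500, 600, 700)
  dirA <- c(1, 0, 0); dirB <- c(0, 1, 0)
  XA <- 0.5 + outer(rnorm(nA, 0, 0.05), dirA) +
    matrix(rnorm(nA * 3, 0, 0.003), nA, 3)
  XB <- 0.5 + outer(rnorm(nB, 0, 0.05), dirB) +
    matrix(rnorm(nB * 3, 0, 0.003), nB, 3)
  coords <- rbind(cbind(runif(nA, 0, 1), runif(nA, 40, 41)),
                  cbind(runif(nB, 8, 9), runif(nB, 48, 49)))
  ds <- spectral_dataset(paste0("s", 1:(nA + nB)), coords, wl,
                         rbind(XA, XB), mode = "reflectance")
  gw <- fit_gwpca(to_absorbance(ds), k = 1, kernel = kernel_spec(300, "haversine"))
  cosab <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  mean_load_A <- rowMeans(gw$loadings[, 1, 1:nA])
  mean_load_B <- rowMeans(gw$loadings[, 1, (nA + 1):(nA + nB)])
  expect_gt(cosab(mean_load_A, dirA), cosab(mean_load_A, dirB))
  expect_gt(cosab(mean_load_B, dirB), cosab(mean_load_B, dirA))
})

test_that("bandwidth selection behaves on homogeneous and structured scenes", {
  # homogeneous scene: the LOO score curve is flat across the upper half
  # of the search range
  sc <- generate_scene(scene_presets("homogeneous"), seed = 5)
  pp <- preprocess(sc$dataset)
  small <- spectral_dataset(pp$ids[1:60], pp$coords[1:60, ],
                            pp$wavelengths, pp$values[1:60, ],
                            mode = pp$mode)
  Xstd <- scale(small$values)
  D <- geo_distances(small$coords, "haversine")
  dmax <- max(D)
  grid <- seq(0.5 * dmax, dmax, length.out = 5)
  scores <- vapply(grid, function(b) gwpca_loo_score(Xstd, D, 2, b),
                   numeric(1))
  expect_lt((max(scores) - min(scores)) / min(scores), 0.01)

  # two-region scene: selected bandwidth below the inter-region distance
  set.seed(9)
  nA <- 25; nB <- 25
  XA <- cbind(rnorm(nA, 0, 1), rnorm(nA, 0, 0.05), rnorm(nA, 0, 0.05))
  XB <- cbind(rnorm(nB, 0, 0.05), rnorm(nB, 0, 1), rnorm(nB, 0, 0.05))
  coords <- rbind(cbind(runif(nA, 0, 0.5), runif(nA, 40, 40.5)),
                  cbind(runif(nB, 8, 8.5), runif(nB, 47, 47.5)))
  Xstd2 <- scale(rbind(XA, XB))
  ks <- select_bandwidth(Xstd2, coords, 1, metric = "haversine")
  inter_region <- geo_distances(rbind(c(0.25, 40.25), c(8.25, 47.25)),
                                "haversine")[1, 2]
  expect_lt(ks$bandwidth, inter_region)
  expect_error(select_bandwidth(Xstd2[1:2, ], coords[1:2, ], 1),
               "k \\+ 2")
})

test_that("too-small bandwidth or degenerate geometry raise informative errors", {
  sc <- small_scene(10)
  pp <- preprocess(sc$dataset)
  expect_error(fit_gwpca(pp, k = 3, kernel = kernel_spec(0.001, "haversine")),
               "bandwidth")
  X <- scale(matrix(rnorm(40), 10, 4))
  co <- matrix(1, 10, 2)
  expect_error(select_bandwidth(X, co, 2), "coincident")
})
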