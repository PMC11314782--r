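#' Fit a partial least squares regression (NIPALS)
#'
#' Latent-variable linear calibration maximizing the covariance between
#' spectra and target. Columns are mean-centred (not scaled); components
#' are extracted by the NIPALS algorithm. With `ncomp = "auto"` the
#' component count minimizing 10-fold cross-validated RMSE over
#' 1..min(30, n-2, m) is chosen; folds are assigned deterministically by
#' interleaving the rank of y, so the choice does not depend on row order
#' or on a random stream.
#'
#' @param X n x m numeric matrix of predictors (preprocessed spectra).
#' @param y numeric response, length n.
#' @param ncomp integer number of latent variables, or `"auto"`.
#' @param max_ncomp cap for the auto search (default 30).
#' @return an object of class `plsr_model`: `coefficients` (length m),
#'   `intercept`, `ncomp`, `x_means`, `y_mean`, `bands`, loadings/weights
#'   of the decomposition, and `cv` (the RMSE curve when auto).
#' @export
fit_plsr <- function(X, y, ncomp = "auto", max_ncomp = 30) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  bands <- colnames(X)
  if (stats::sd(y) == 0) {
    warning("constant response: returning an intercept-only model")
    return(structure(list(coefficients = rep(0, m), intercept = y[1],
                          ncomp = 0L, x_means = colMeans(X), y_mean = y[1],
                          bands = bands, W = NULL, P = NULL, q = NULL,
                          cv = NULL),
                     class = "plsr_model"))
  }
  cv <- NULL
  if (identical(ncomp, "auto")) {
    if (n < 4) stop("auto component selection needs n >= 4")
    amax <- min(max_ncomp, n - 2, m)
    nf <- min(10, n)
    folds <- (rank(y, ties.method = "first") - 1) %% nf + 1
    press <- matrix(NA_real_, nf, amax)
    for (f in seq_len(nf)) {
      tr <- folds != f
      if (sum(tr) < 2 || stats::sd(y[tr]) == 0) next
      a_f <- min(amax, sum(tr) - 1)
      fit <- nipals_pls(X[tr, , drop = FALSE], y[tr], a_f)
      for (a in seq_len(a_f)) {
        B <- pls_coef(fit, a)
        pred <- X[!tr, , drop = FALSE] %*% B$beta + B$intercept
        press[f, a] <- sum((y[!tr] - pred)^2)
      }
    }
    rmse_cv <- sqrt(colSums(press, na.rm = TRUE) / n)
    ncomp <- which.min(rmse_cv)
    cv <- data.frame(ncomp = seq_len(amax), rmse_cv = rmse_cv)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, m))
    stop("ncomp must be in 1..min(n-1, m)")
  fit <- nipals_pls(X, y, ncomp)
  ncomp <- min(ncomp, ncol(fit$W))  # deflation may exhaust X early
  B <- pls_coef(fit, ncomp)
  structure(list(coefficients = as.numeric(B$beta), intercept = B$intercept,
                 ncomp = ncomp, x_means = fit$x_means, y_mean = fit$y_mean,
                 bands = bands, W = fit$W, P = fit$P, q = fit$q, cv = cv),
            class = "plsr_model")
}

# NIPALS decomposition for a univariate response; returns weights W,
# X-loadings P, y-loadings q and the centring constants
nipals_pls <- function(X, y, a) {
  x_means <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_means)
  f <- y - y_mean
  m <- ncol(X)
  W <- matrix(0, m, a); P <- matrix(0, m, a); q <- numeric(a)
  used <- 0
  for (h in seq_len(a)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- crossprod(E, t) / tt
    qh <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * qh
    W[, h] <- w; P[, h] <- p; q[h] <- qh
    used <- h
  }
  list(W = W[, seq_len(max(used, 1)), drop = FALSE],
       P = P[, seq_len(max(used, 1)), drop = FALSE],
       q = q[seq_len(max(used, 1))],
       x_means = x_means, y_mean = y_mean)
}

# regression vector using the first a components: B = W (P'W)^-1 q
pls_coef <- function(fit, a) {
  a <- min(a, ncol(fit$W))
  Wa <- fit$W[, seq_len(a), drop = FALSE]
  Pa <- fit$P[, seq_len(a), drop = FALSE]
  qa <- fit$q[seq_len(a)]
  beta <- Wa %*% solve(crossprod(Pa, Wa), qa)
  list(beta = beta, intercept = fit$y_mean - sum(fit$x_means * beta))
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("<plsr_model> ", length(x$coefficients), " bands, ", x$ncomp,
      " latent variable(s)\n", sep = "")
  invisible(x)
}

#' Fit an M5-style model tree
#'
#' A piecewise multivariate linear model: recursive binary splits on single
#' bands chosen to maximize the standard-deviation reduction
#' SDR = sd(S) - sum(|S_i|/|S|) sd(S_i), with multivariate linear models in
#' the leaves. Splitting stops when a node holds fewer than `2 * min_leaf`
#' samples, when its response spread falls below `sd_frac` of the root
#' spread, or when no split improves SDR. Leaf (and internal) models are
#' least-squares fits on the bands used on the node's path plus the bands
#' most correlated with the response, capped so the design stays
#' well-posed; ill-conditioned systems fall back to a light ridge
#' (lambda = 1e-6 trace). Predictions are smoothed up the path in the M5
#' manner with constant `smoothing_k` (0 disables smoothing), and subtrees
#' whose pessimistically adjusted error exceeds their node model's are
#' pruned when `prune = TRUE`.
#'
#' @param X n x m predictor matrix.
#' @param y numeric response.
#' @param min_leaf minimum samples per leaf (default 20).
#' @param sd_frac stop threshold as a fraction of root sd (default 0.05).
#' @param smoothing_k M5 smoothing constant (default 15).
#' @param prune logical (default TRUE).
#' @return an object of class `model_tree`.
#' @export
fit_model_tree <- function(X, y, min_leaf = 20, sd_frac = 0.05,
                           smoothing_k = 15, prune = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n < 2) stop("need at least 2 samples")
  root_sd <- sd_pop(y)
  root <- grow_node(X, y, seq_len(n), integer(0), min_leaf, sd_frac, root_sd)
  if (prune) root <- prune_node(root, X, y)
  structure(list(root = root, bands = colnames(X), m = ncol(X),
                 smoothing_k = smoothing_k, min_leaf = min_leaf,
                 n_train = n),
            class = "model_tree")
}

sd_pop <- function(y) sqrt(mean((y - mean(y))^2))

# linear model at a node: path bands + top-|cor| bands, capped
node_linear_model <- function(X, y, idx, path_bands) {
  n <- length(idx)
  m <- ncol(X)
  cap <- max(3L, floor(n / 8))
  cap <- min(cap, n - 2L, m)
  cap <- max(cap, 1L)
  if (stats::sd(y[idx]) == 0) {
    return(list(bands = integer(0), beta = numeric(0), intercept = y[idx][1]))
  }
  cors <- suppressWarnings(abs(stats::cor(X[idx, , drop = FALSE], y[idx])))
  cors[!is.finite(cors)] <- 0
  ranked <- order(cors, decreasing = TRUE)
  bands <- unique(c(path_bands, ranked))[seq_len(min(cap, m))]
  Xs <- X[idx, bands, drop = FALSE]
  Xc <- sweep(Xs, 2, colMeans(Xs))
  yc <- y[idx] - mean(y[idx])
  G <- crossprod(Xc)
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    lam <- 1e-6 * sum(diag(G))
    if (lam <= 0) lam <- 1e-8
    beta <- solve(G + diag(lam, ncol(G)), crossprod(Xc, yc))
  } else {
    beta <- solve(qrG, crossprod(Xc, yc))
  }
  list(bands = bands, beta = as.numeric(beta),
       intercept = mean(y[idx]) - sum(colMeans(Xs) * beta))
}

node_predict_one <- function(model, x) {
  if (length(model$bands) == 0) return(model$intercept)
  sum(x[model$bands] * model$beta) + model$intercept
}

grow_node <- function(X, y, idx, path_bands, min_leaf, sd_frac, root_sd) {
  n <- length(idx)
  node <- list(n = n, model = node_linear_model(X, y, idx, path_bands),
               idx = idx)
  if (n < 2 * min_leaf || sd_pop(y[idx]) < sd_frac * root_sd) {
    node$leaf <- TRUE
    return(node)
  }
  best <- find_best_split(X, y, idx, min_leaf)
  if (is.null(best)) {
    node$leaf <- TRUE
    return(node)
  }
  node$leaf <- FALSE
  node$split_band <- best$band
  node$threshold <- best$threshold
  left <- idx[X[idx, best$band] <= best$threshold]
  right <- idx[X[idx, best$band] > best$threshold]
  child_path <- c(path_bands, best$band)
  node$left <- grow_node(X, y, left, child_path, min_leaf, sd_frac, root_sd)
  node$right <- grow_node(X, y, right, child_path, min_leaf, sd_frac, root_sd)
  node
}

# best (band, threshold) by SDR using cumulative sums; O(m n log n)
find_best_split <- function(X, y, idx, min_leaf) {
  n <- length(idx)
  yv <- y[idx]
  sd_all <- sd_pop(yv)
  best <- NULL
  best_sdr <- 0
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    ord <- order(xv)
    xs <- xv[ord]; ys <- yv[ord]
    cs <- cumsum(ys); css <- cumsum(ys^2)
    tot <- cs[n]; tots <- css[n]
    i <- seq_len(n - 1)
    nl <- i; nr <- n - i
    varl <- pmax(css[i] / nl - (cs[i] / nl)^2, 0)
    varr <- pmax((tots - css[i]) / nr - ((tot - cs[i]) / nr)^2, 0)
    sdr <- sd_all - (nl / n) * sqrt(varl) - (nr / n) * sqrt(varr)
    ok <- nl >= min_leaf & nr >= min_leaf & xs[i] < xs[i + 1]
    if (!any(ok)) next
    sdr[!ok] <- -Inf
    i_best <- which.max(sdr)
    if (sdr[i_best] > best_sdr + 1e-12) {
      best_sdr <- sdr[i_best]
      best <- list(band = j,
                   threshold = (xs[i_best] + xs[i_best + 1]) / 2,
                   sdr = sdr[i_best])
    }
  }
  best
}

# M5-style pruning: collapse a subtree when the node model's pessimistic
# error is no worse than the subtree's
prune_node <- function(node, X, y) {
  if (node$leaf) return(node)
  node$left <- prune_node(node$left, X, y)
  node$right <- prune_node(node$right, X, y)
  idx <- node$idx
  adj <- function(sse, n, v) {
    n <- max(n, v + 1)
    sqrt(sse / n) * (n + v) / (n - v)
  }
  own_pred <- vapply(idx, function(i) node_predict_one(node$model, X[i, ]),
                     numeric(1))
  own_err <- adj(sum((y[idx] - own_pred)^2), length(idx),
                 length(node$model$bands) + 1)
  sub_pred <- vapply(idx, function(i) tree_predict_raw(node, X[i, ]),
                     numeric(1))
  sub_err <- adj(sum((y[idx] - sub_pred)^2), length(idx),
                 count_params(node))
  if (own_err <= sub_err) {
    node <- list(n = node$n, model = node$model, idx = idx, leaf = TRUE)
  }
  node
}

count_params <- function(node) {
  if (node$leaf) return(length(node$model$bands) + 1)
  1 + count_params(node$left) + count_params(node$right)
}

# unsmoothed routing prediction (used during pruning)
tree_predict_raw <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$split_band] <= node$threshold) node$left else node$right
  }
  node_predict_one(node$model, x)
}

tree_predict_smoothed <- function(node, x, k) {
  path <- list()
  nd <- node
  while (!nd$leaf) {
    path[[length(path) + 1]] <- nd
    nd <- if (x[nd$split_band] <= nd$threshold) nd$left else nd$right
  }
  p <- node_predict_one(nd$model, x)
  n_below <- nd$n
  for (a in rev(seq_along(path))) {
    anc <- path[[a]]
    p <- (n_below * p + k * node_predict_one(anc$model, x)) / (n_below + k)
    n_below <- anc$n
  }
  p
}

#' @export
print.model_tree <- function(x, ...) {
  cat("<model_tree> ", x$n_train, " training samples, ",
      count_leaves(x$root), " leaf model(s)\n", sep = "")
  invisible(x)
}

count_leaves <- function(node) {
  if (node$leaf) return(1L)
  count_leaves(node$left) + count_leaves(node$right)
}

#' Predict from a calibration model
#'
#' Both model classes check the band layout of `newdata` against the
#' training layout: when both carry band (column) names, columns are
#' matched by name and may appear in any order; otherwise the band count
#' must match. Predictions stay on the training scale of the response
#' (log SOC when the target was log-transformed); `inverse = exp` (or any
#' function) back-transforms on request.
#'
#' @param object a `plsr_model` or `model_tree`.
#' @param newdata matrix (or single row) of spectra.
#' @param inverse optional function applied to the predictions.
#' @param smoothing override the tree's smoothing constant (`model_tree`
#'   only).
#' @param ... unused.
#' @return numeric vector, one prediction per row.
#' @export
predict.plsr_model <- function(object, newdata, inverse = NULL, ...) {
  X <- align_bands(newdata, object$bands, length(object$coefficients))
  p <- as.numeric(X %*% object$coefficients + object$intercept)
  if (!is.null(inverse)) p <- inverse(p)
  p
}

#' @rdname predict.plsr_model
#' @export
predict.model_tree <- function(object, newdata, inverse = NULL,
                               smoothing = NULL, ...) {
  X <- align_bands(newdata, object$bands, object$m)
  k <- if (is.null(smoothing)) object$smoothing_k else smoothing
  p <- vapply(seq_len(nrow(X)), function(i) {
    if (k > 0) tree_predict_smoothed(object$root, X[i, ], k)
    else tree_predict_raw(object$root, X[i, ])
  }, numeric(1))
  if (!is.null(inverse)) p <- inverse(p)
  p
}

align_bands <- function(newdata, bands, m_expected) {
  X <- newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (!is.null(bands) && !is.null(colnames(X))) {
    if (!setequal(colnames(X), bands))
      stop("band layout of newdata does not match the training grid")
    X <- X[, bands, drop = FALSE]
  } else if (!is.na(m_expected) && ncol(X) != m_expected) {
    stop("newdata has ", ncol(X), " bands; model was trained on ",
         m_expected)
  }
  X
}

#' Fit one calibration model per group plus a pooled global model
#'
#' Within every group (spectral cluster or stratum) of sufficient size the
#' samples are split 2:1 by Kennard-Stone on the preprocessed spectra and
#' the chosen model is fitted on the calibration part; a pooled model over
#' all samples (with its own KS split) provides the "All" comparison.
#' Undersized groups are excluded with a warning and recorded.
#'
#' @param ds a `spectral_dataset` whose `target` is the modeling response
#'   (already log-transformed when desired).
#' @param labels group label per sample (cluster id or stratum).
#' @param model `"plsr"` or `"cubist"` (the M5-style model tree).
#' @param min_size minimum group size (default 30).
#' @param ratio KS calibration:validation ratio (default `c(2, 1)`).
#' @param ... passed to the model fitting function.
#' @return an object of class `grouped_calibration`: `groups` (named list
#'   of `idx`, `split`, `model`), `global` (`split`, `model`), `model_name`,
#'   `excluded`.
#' @export
fit_per_group <- function(ds, labels, model = c("plsr", "cubist"),
                          min_size = 30, ratio = c(2, 1), ...) {
  model <- match.arg(model)
  if (is.null(ds$target)) stop("dataset has no target")
  if (length(labels) == 0 || length(labels) != n_samples(ds))
    stop("labels must have one entry per sample")
  fit_fun <- function(X, y) {
    if (model == "plsr") fit_plsr(X, y, ...) else fit_model_tree(X, y, ...)
  }
  groups <- list()
  excluded <- character(0)
  for (g in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == g)
    if (length(idx) < min_size) {
      warning("group '", g, "' has ", length(idx),
              " samples (< ", min_size, "); excluded")
      excluded <- c(excluded, g)
      next
    }
    split <- kennard_stone_split(ds$values[idx, , drop = FALSE], ratio)
    fit <- fit_fun(ds$values[idx[split$cal], , drop = FALSE],
                   ds$target[idx[split$cal]])
    groups[[g]] <- list(idx = idx, split = split, model = fit)
  }
  if (length(groups) == 0) stop("no group meets the minimum size")
  gsplit <- kennard_stone_split(ds$values, ratio)
  gmodel <- fit_fun(ds$values[gsplit$cal, , drop = FALSE],
                    ds$target[gsplit$cal])
  structure(list(groups = groups,
                 global = list(split = gsplit, model = gmodel),
                 model_name = model, excluded = excluded),
            class = "grouped_calibration")
}
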