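#' Kennard-Stone calibration/validation split
#'
#' Deterministic greedy max-min selection in spectral space: the first two
#' calibration samples are the pair at maximum Euclidean distance; each
#' subsequent sample maximizes its minimum distance to the already selected
#' set. Ties break toward the lowest row index. The calibration set covers
#' the feature space uniformly; the remainder forms the validation set.
#'
#' @param X n x m numeric matrix (preprocessed spectra; the model inputs).
#' @param ratio calibration:validation ratio as a length-2 vector
#'   (default `c(2, 1)`). Calibration size = `ceiling(n * cal/(cal+val))`.
#' @return an object of class `ks_split`: integer vectors `cal` and `val`
#'   (disjoint, covering 1..n), `ratio`, `metric`.
#' @export
kennard_stone_split <- function(X, ratio = c(2, 1)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("Kennard-Stone needs at least 3 samples")
  if (length(ratio) != 2 || any(ratio <= 0)) stop("ratio must be two positive numbers")
  n_cal <- ceiling(n * ratio[1] / sum(ratio))
  n_cal <- min(max(n_cal, 2L), n - 1L)
  D <- as.matrix(stats::dist(X))
  # seed pair: maximum pairwise distance, ties by lowest (i, j)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  dmax <- max(D)
  cand <- ut[D[ut] == dmax, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- c(cand[1, 1], cand[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind)  # which.max takes the first (lowest-index) maximum
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sel <- as.integer(sel)
  structure(list(cal = sel, val = setdiff(seq_len(n), sel),
                 ratio = ratio, metric = "euclidean"),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat("<ks_split> ", length(x$cal), " calibration / ", length(x$val),
      " validation (ratio ", x$ratio[1], ":", x$ratio[2], ")\n", sep = "")
  invisible(x)
}
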