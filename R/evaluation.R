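#' Validation metrics: RMSE, R-squared, RPIQ
#'
#' `rmse` is the root mean squared error; `r2` is 1 - SSE/SST with SST
#' about the observed mean; `rpiq` is the ratio of performance to
#' inter-quartile distance, IQR(obs)/RMSE, with type-7
#' (linear-interpolation) quantiles. A perfect fit gives RPIQ = `Inf`;
#' constant observations give R-squared `NaN`.
#'
#' @param obs,pred numeric vectors of equal length >= 2.
#' @return a single number.
#' @export
rmse <- function(obs, pred) {
  check_obs_pred(obs, pred)
  sqrt(mean((obs - pred)^2))
}

#' @rdname rmse
#' @export
r2 <- function(obs, pred) {
  check_obs_pred(obs, pred)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NaN)
  1 - sum((obs - pred)^2) / sst
}

#' @rdname rmse
#' @export
rpiq <- function(obs, pred) {
  check_obs_pred(obs, pred)
  e <- rmse(obs, pred)
  iqr <- unname(diff(stats::quantile(obs, c(0.25, 0.75), type = 7)))
  if (e == 0) return(Inf)
  iqr / e
}

check_obs_pred <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2) stop("need at least 2 observations")
  if (anyNA(obs) || anyNA(pred)) stop("NA in obs or pred")
  invisible(NULL)
}

#' RPIQ quality category
#'
#' Classifies a model by its RPIQ: `< 1.5` very bad, `[1.5, 2.0)` poor,
#' `[2.0, 2.5]` good, `> 2.5` very good.
#'
#' @param v non-negative RPIQ value(s).
#' @return character vector of categories.
#' @export
rpiq_category <- function(v) {
  if (any(v < 0)) stop("RPIQ cannot be negative")
  out <- character(length(v))
  out[v < 1.5] <- "very bad"
  out[v >= 1.5 & v < 2.0] <- "poor"
  out[v >= 2.0 & v <= 2.5] <- "good"
  out[v > 2.5] <- "very good"
  out
}

# half-up decimal rounding (the convention of printed report tables;
# base round() is half-even, which turns 0.475 into 0.47)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Append the mean row to a grouped report
#'
#' The mean row is the unweighted arithmetic mean of the group rows,
#' computed on the displayed (rounded) cells so that a printed report is
#' self-consistent: the mean row is exactly reproducible from the group
#' rows it accompanies. Cells use half-up decimal rounding, the convention
#' of printed calibration tables. Rows named "All" (the pooled model) are
#' not averaged.
#'
#' @param df data frame with a `group` column and numeric metric columns
#'   (`n` is rounded to integer, others to `digits`).
#' @param digits decimal places for the metric cells (default 2).
#' @return the data frame with group cells rounded and a "Mean" row added.
#' @export
add_mean_row <- function(df, digits = 2) {
  if (!"group" %in% names(df)) stop("df must have a 'group' column")
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  grp <- df[df$group != "All", , drop = FALSE]
  for (cl in num_cols)
    df[[cl]] <- round_half_up(df[[cl]], if (cl == "n") 0 else digits)
  mean_row <- df[1, , drop = FALSE]
  mean_row[1, ] <- NA
  mean_row$group <- "Mean"
  for (cl in num_cols) {
    v <- mean(round_half_up(grp[[cl]], if (cl == "n") 0 else digits))
    mean_row[[cl]] <- round_half_up(v, if (cl == "n") 0 else digits)
  }
  if ("model" %in% names(df)) mean_row$model <- df$model[1]
  if ("category" %in% names(df))
    mean_row$category <- rpiq_category(mean_row$rpiq)
  rownames(mean_row) <- NULL
  rbind(df, mean_row)
}

#' Evaluate a grouped calibration on its validation sets
#'
#' Computes per-group validation R-squared, RMSE and RPIQ (on the response
#' scale the models were trained on, i.e. log SOC under the default
#' pipeline), the pooled "All" row from the global model's own validation
#' set, and the unweighted mean row over the groups. Groups with fewer
#' than 2 validation samples are excluded with a warning.
#'
#' @param gc a [fit_per_group()] result.
#' @param ds the `spectral_dataset` the calibration was fitted on.
#' @param digits display rounding for the report table (default 2).
#' @return an object of class `grouped_report`: `table` (rounded, with
#'   "All" and "Mean" rows), `raw` (unrounded per-group metrics).
#' @export
evaluate_grouped <- function(gc, ds, digits = 2) {
  rows <- list()
  for (g in names(gc$groups)) {
    grp <- gc$groups[[g]]
    vidx <- grp$idx[grp$split$val]
    if (length(vidx) < 2) {
      warning("group '", g, "' has fewer than 2 validation samples; excluded")
      next
    }
    obs <- ds$target[vidx]
    pred <- stats::predict(grp$model, ds$values[vidx, , drop = FALSE])
    rows[[g]] <- data.frame(group = g, n = length(grp$idx),
                            model = gc$model_name,
                            r2 = r2(obs, pred), rmse = rmse(obs, pred),
                            rpiq = rpiq(obs, pred))
  }
  if (length(rows) == 0) stop("no group has enough validation samples")
  raw <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  vall <- gc$global$split$val
  obs <- ds$target[vall]
  pred <- stats::predict(gc$global$model, ds$values[vall, , drop = FALSE])
  all_row <- data.frame(group = "All", n = n_samples(ds),
                        model = gc$model_name,
                        r2 = r2(obs, pred), rmse = rmse(obs, pred),
                        rpiq = rpiq(obs, pred))
  tab <- rbind(all_row, raw)
  tab$category <- rpiq_category(tab$rpiq)
  tab <- add_mean_row(tab, digits)
  structure(list(table = tab, raw = raw), class = "grouped_report")
}

#' @export
print.grouped_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Random-forest permutation importance per band
#'
#' Fits a regression random forest and reports the out-of-bag permutation
#' importance (mean OOB MSE increase when a band is permuted) for every
#' wavelength. Permutation importance is preferred over impurity
#' importance, which is biased for strongly correlated spectral bands.
#'
#' @param X n x m spectral matrix (n >= 30).
#' @param y numeric response.
#' @param wavelengths band centres in nm (default: numeric column names).
#' @param ntree number of trees (default 500).
#' @param mtry variables tried per split (default `floor(m/3)`).
#' @param seed RNG seed for the forest.
#' @return an object of class `importance_profile`: data frame `profile`
#'   (wavelength, importance) plus the forest parameters.
#' @export
band_importance_rf <- function(X, y, wavelengths = NULL, ntree = 500,
                               mtry = NULL, seed = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 bands")
  if (nrow(X) < 30) stop("need at least 30 samples")
  if (is.null(wavelengths))
    wavelengths <- suppressWarnings(as.numeric(colnames(X)))
  if (is.null(mtry)) mtry <- max(1, floor(ncol(X) / 3))
  df <- as.data.frame(X)
  names(df) <- paste0("b", seq_len(ncol(X)))
  df$.y <- y
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = ntree, mtry = mtry,
                        importance = "permutation", seed = seed,
                        num.threads = 1)
  structure(list(
    profile = data.frame(wavelength = wavelengths,
                         importance = unname(fit$variable.importance)),
    ntree = ntree, mtry = mtry, seed = seed
  ), class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  top <- x$profile[order(-x$profile$importance), ][1:min(5, nrow(x$profile)), ]
  cat("<importance_profile> ", nrow(x$profile), " bands (ntree=", x$ntree,
      ", mtry=", x$mtry, "); top bands:\n", sep = "")
  print(top, row.names = FALSE)
  invisible(x)
}
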