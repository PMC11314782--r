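#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds a soil spectral library in wide form: one row
#' per sample with its identifier, geographic coordinates, a spectral matrix
#' on a common wavelength grid, and (optionally) the soil organic carbon
#' target and a categorical stratum label such as land cover.
#'
#' @param ids character or integer vector of sample identifiers (unique).
#' @param coords numeric matrix `n x 2` of (lon, lat) in decimal degrees.
#' @param wavelengths strictly increasing numeric grid in nm.
#' @param values numeric `n x m` matrix of reflectance (in (0,1]) or
#'   absorbance, according to `mode`.
#' @param target optional numeric vector of SOC in g/kg, length n.
#' @param strata optional categorical label per sample.
#' @param mode `"reflectance"` or `"absorbance"`.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(ids, coords, wavelengths, values,
                             target = NULL, strata = NULL,
                             mode = c("reflectance", "absorbance")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  coords <- as.matrix(coords)
  n <- nrow(values)
  m <- ncol(values)
  if (length(ids) != n)
    stop("length(ids) [", length(ids), "] != rows of values [", n, "]")
  if (anyDuplicated(ids))
    stop("sample ids must be unique")
  if (nrow(coords) != n || ncol(coords) != 2)
    stop("coords must be an n x 2 (lon, lat) matrix")
  if (length(wavelengths) != m)
    stop("length(wavelengths) [", length(wavelengths),
         "] != columns of values [", m, "]")
  if (m > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectral values contain NA or non-finite entries")
  if (anyNA(coords)) stop("coordinates contain NA")
  if (mode == "reflectance" && (any(values <= 0) || any(values > 1))) {
    bad <- which(apply(values, 1, function(r) any(r <= 0 | r > 1)))
    stop("reflectance values outside (0, 1] for sample(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  if (!is.null(target)) {
    if (length(target) != n) stop("length(target) != n")
    if (anyNA(target)) stop("target contains NA")
  }
  if (!is.null(strata) && length(strata) != n)
    stop("length(strata) != n")
  structure(list(
    ids = as.character(ids),
    coords = coords,
    wavelengths = as.numeric(wavelengths),
    values = values,
    target = target,
    strata = if (is.null(strata)) NULL else as.character(strata),
    mode = mode
  ), class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", nrow(x$values), " samples x ",
      length(x$wavelengths), " bands (", x$mode, "), ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm",
      if (!is.null(x$target)) ", with SOC target" else "",
      if (!is.null(x$strata)) ", with strata" else "", "\n", sep = "")
  invisible(x)
}

#' Number of samples / bands
#' @param ds a `spectral_dataset`
#' @return integer
#' @export
n_samples <- function(ds) nrow(ds$values)

#' @rdname n_samples
#' @export
n_bands <- function(ds) length(ds$wavelengths)

#' Read a wide-format spectral library table
#'
#' Expects a CSV with header `id, lon, lat, soc, [stratum]` followed by
#' numeric wavelength-named reflectance/absorbance columns (e.g. `400`,
#' `410`, ...). Wavelength columns may appear in any order; they are sorted
#' ascending. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @param mode spectral mode of the stored values.
#' @param target_col,stratum_col column names for the target and the
#'   optional stratum label.
#' @return a [spectral_dataset()].
#' @export
read_spectra_table <- function(path, mode = c("reflectance", "absorbance"),
                               target_col = "soc", stratum_col = "stratum") {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  for (col in c("id", "lon", "lat"))
    if (!col %in% nm) stop("required column '", col, "' missing in ", path)
  wl_cols <- nm[!is.na(suppressWarnings(as.numeric(nm)))]
  if (length(wl_cols) == 0) stop("no numeric wavelength columns found in ", path)
  wl <- as.numeric(wl_cols)
  ord <- order(wl)
  wl_cols <- wl_cols[ord]
  wl <- wl[ord]
  vals <- as.matrix(df[, wl_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[wl_cols], is.numeric, logical(1)))
    stop("non-numeric spectral values in column(s): ",
         paste(wl_cols[bad], collapse = ", "))
  }
  colnames(vals) <- wl_cols
  spectral_dataset(
    ids = df$id,
    coords = cbind(lon = df$lon, lat = df$lat),
    wavelengths = wl,
    values = vals,
    target = if (target_col %in% nm) df[[target_col]] else NULL,
    strata = if (stratum_col %in% nm) df[[stratum_col]] else NULL,
    mode = mode
  )
}

#' Write a spectral dataset as a wide CSV
#'
#' Inverse of [read_spectra_table()]: columns `id, lon, lat, soc,
#' [stratum]`, then one column per wavelength.
#'
#' @param ds a `spectral_dataset`.
#' @param path output path.
#' @export
write_spectra_table <- function(ds, path) {
  df <- data.frame(id = ds$ids, lon = ds$coords[, 1], lat = ds$coords[, 2],
                   check.names = FALSE)
  if (!is.null(ds$target)) df$soc <- ds$target
  if (!is.null(ds$strata)) df$stratum <- ds$strata
  sp <- as.data.frame(ds$values)
  names(sp) <- format(ds$wavelengths, trim = TRUE, scientific = FALSE)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample spectra to a coarser regular grid
#'
#' Each output band centred at wavelength w is the mean of the native
#' channels falling in the half-open window `[w - interval/2, w + interval/2)`,
#' clipped to the native range. Window averaging (rather than interpolation)
#' is the robust choice when downsampling a fine grid (e.g. 0.5 nm to
#' 10 nm); linear interpolation at the output centres is available via
#' `method = "interpolate"`.
#'
#' @param ds a `spectral_dataset` on a regular native grid.
#' @param interval output spacing in nm (must exceed the native spacing).
#' @param method `"window"` (default) or `"interpolate"`.
#' @return a `spectral_dataset` on the grid `seq(min(wl), max(wl), by = interval)`.
#' @export
resample_spectra <- function(ds, interval, method = c("window", "interpolate")) {
  method <- match.arg(method)
  wl <- ds$wavelengths
  if (length(wl) < 2) stop("cannot resample a single-band dataset")
  spacing <- diff(wl)
  if (max(spacing) - min(spacing) > 1e-8)
    stop("native grid is not regular")
  if (interval < spacing[1] - 1e-12)
    stop("interval (", interval, " nm) finer than native spacing (",
         spacing[1], " nm)")
  new_wl <- seq(wl[1], wl[length(wl)], by = interval)
  if (method == "interpolate") {
    out <- t(apply(ds$values, 1, function(r)
      stats::approx(wl, r, xout = new_wl)$y))
  } else {
    # half-open windows [w - i/2, w + i/2); assign each native channel to
    # its window index, then average with a grouped rowsum
    idx <- floor((wl - new_wl[1]) / interval + 0.5) + 1
    idx[idx < 1] <- 1
    idx[idx > length(new_wl)] <- length(new_wl)
    counts <- tabulate(idx, nbins = length(new_wl))
    if (any(counts == 0))
      stop("internal: empty resampling window; check grid regularity")
    out <- t(rowsum(t(ds$values), group = idx)) /
      rep(counts, each = nrow(ds$values))
  }
  colnames(out) <- format(new_wl, trim = TRUE, scientific = FALSE)
  spectral_dataset(ds$ids, ds$coords, new_wl, out,
                   target = ds$target, strata = ds$strata, mode = ds$mode)
}

#' Convert reflectance to absorbance
#'
#' Applies the spectroscopic absorbance transform A = log10(1/R)
#' elementwise. Requires reflectance in (0, 1].
#'
#' @param ds a `spectral_dataset` in reflectance mode.
#' @return the dataset in absorbance mode.
#' @export
to_absorbance <- function(ds) {
  if (ds$mode != "reflectance")
    stop("dataset is already in absorbance mode")
  if (any(ds$values <= 0)) {
    bad <- which(apply(ds$values, 1, function(r) any(r <= 0)))
    stop("non-positive reflectance for sample(s): ",
         paste(utils::head(ds$ids[bad], 5), collapse = ", "))
  }
  spectral_dataset(ds$ids, ds$coords, ds$wavelengths, log10(1 / ds$values),
                   target = ds$target, strata = ds$strata, mode = "absorbance")
}

#' Savitzky-Golay smoothing
#'
#' Smooths each spectrum with a moving local polynomial fit. The first and
#' last `(window-1)/2` bands are filled from the polynomial fitted to the
#' nearest full window, so the band count is unchanged.
#'
#' @param ds a `spectral_dataset`.
#' @param window odd window length in channels (default 15).
#' @param order polynomial order (default 2), must be `< window`.
#' @return the smoothed dataset (same mode and grid).
#' @export
savgol_smooth <- function(ds, window = 15, order = 2) {
  m <- n_bands(ds)
  if (window %% 2 == 0) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  if (window > m) stop("window (", window, ") exceeds band count (", m, ")")
  out <- t(apply(ds$values, 1, signal::sgolayfilt, p = order, n = window))
  colnames(out) <- colnames(ds$values)
  if (ds$mode == "reflectance") {
    # smoothing can ring slightly above 1 or below 0 on extreme spectra
    out[out > 1] <- 1
    eps <- .Machine$double.eps
    out[out <= 0] <- eps
  }
  spectral_dataset(ds$ids, ds$coords, ds$wavelengths, out,
                   target = ds$target, strata = ds$strata, mode = ds$mode)
}

#' Natural-log transform of the SOC target
#'
#' SOC distributions in large libraries are strongly right-skewed; modeling
#' is done on ln(SOC). Values below a positivity floor cannot be
#' log-transformed meaningfully and are dropped (the alternative, adding an
#' offset, would silently change the model space).
#'
#' @param y numeric vector of SOC in g/kg.
#' @param floor positivity floor in g/kg; samples with `y < floor` are
#'   dropped (default 0.1).
#' @return a list with `log_y` (ln of kept values), `kept` (logical mask of
#'   retained samples) and `n_dropped`.
#' @export
log_transform_target <- function(y, floor = 0.1) {
  if (anyNA(y) || any(!is.finite(y))) stop("target contains non-finite values")
  keep <- y >= floor
  if (!any(keep)) stop("all samples fall below the positivity floor")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " sample(s) below the SOC floor of ", floor,
            " g/kg dropped before log transform")
  list(log_y = log(y[keep]), kept = keep, n_dropped = n_drop)
}

#' Moment summary of a target variable
#'
#' Reports mean, median, sd, min, max and the moment coefficients of
#' skewness and kurtosis: g1 = m3 / m2^1.5, raw kurtosis b2 = m4 / m2^2 and
#' excess kurtosis g2 = b2 - 3 (central moments with denominator n). For a
#' constant input sd is 0 and the shape coefficients are `NaN`.
#'
#' @param y numeric vector, length >= 2.
#' @return a list of class `summary_stats`.
#' @export
describe_target <- function(y) {
  if (length(y) < 2) stop("need at least 2 observations")
  if (anyNA(y)) stop("y contains NA")
  n <- length(y)
  mu <- mean(y)
  m2 <- mean((y - mu)^2)
  m3 <- mean((y - mu)^3)
  m4 <- mean((y - mu)^4)
  if (m2 == 0) {
    skew <- NaN; kurt_raw <- NaN; kurt_excess <- NaN
  } else {
    skew <- m3 / m2^1.5
    kurt_raw <- m4 / m2^2
    kurt_excess <- kurt_raw - 3
  }
  structure(list(
    n = n, mean = mu, median = stats::median(y), sd = stats::sd(y),
    min = min(y), max = max(y),
    skewness = skew, kurtosis_raw = kurt_raw, kurtosis_excess = kurt_excess
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "n=%d  mean=%.3g  median=%.3g  sd=%.3g  range=[%.3g, %.3g]\nskewness=%.3g  kurtosis (raw)=%.3g  (excess)=%.3g\n",
    x$n, x$mean, x$median, x$sd, x$min, x$max,
    x$skewness, x$kurtosis_raw, x$kurtosis_excess))
  invisible(x)
}
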