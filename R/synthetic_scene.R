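#' Configuration for a synthetic spatially structured spectral scene
#'
#' Defines a spatially clustered soil spectral library: each cluster has a
#' spatial centre on a synthetic region of roughly 10 x 10 degrees, a
#' smooth endmember absorbance curve (sloping baseline plus Gaussian
#' absorption features, by default near 650, 1400, 1900 and 2200 nm — the
#' iron-oxide, hydroxyl, water and clay features of real soil spectra), a
#' lognormal SOC
#' distribution, and a coupling coefficient tying SOC to the spectrum:
#' higher SOC adds absorbance (darkens the soil, mostly in the visible
#' range by default), so reflectance correlates negatively with SOC. Wavelength-correlated (Gaussian-process) noise with
#' a 50 nm length scale emulates smooth instrument/sample noise.
#'
#' @param n_per_cluster samples per cluster (scalar or per-cluster vector).
#' @param centers k x 2 matrix of cluster (lon, lat) spatial centres.
#' @param spread sd of sample coordinates around their centre, degrees.
#' @param baseline per-cluster absorbance baseline intercept.
#' @param baseline_slope per-cluster baseline slope over the grid.
#' @param feature_centers absorption feature centres, nm.
#' @param feature_width Gaussian feature sd, nm.
#' @param feature_depths k x length(feature_centers) matrix of depths.
#' @param soc_meanlog,soc_sdlog per-cluster lognormal SOC parameters
#'   (mean and sd of ln SOC, SOC in g/kg).
#' @param coupling per-cluster absorbance added per unit ln SOC (> 0:
#'   higher SOC -> higher absorbance -> lower reflectance).
#' @param coupling_shape optional per-wavelength profile of the SOC
#'   coupling (length of `wavelengths`); default flat. A localized shape
#'   plants the SOC signal in a known spectral region.
#' @param noise_sd sd of the correlated spectral noise (absorbance units).
#' @param noise_lengthscale noise correlation length along wavelength, nm.
#' @param wavelengths output grid, nm (default 400-2500 at 10 nm).
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_per_cluster = 250,
                         centers = matrix(c(2.5, 42.5, 7.5, 42.5,
                                            2.5, 47.5, 7.5, 47.5),
                                          ncol = 2, byrow = TRUE),
                         spread = 0.8,
                         baseline = c(0.65, 0.35, 0.35, 0.65),
                         baseline_slope = c(0.37, 0.13, 0.37, 0.13),
                         feature_centers = c(650, 1400, 1900, 2200),
                         feature_width = 70,
                         feature_depths = NULL,
                         soc_meanlog = c(3.15, 3.24, 2.99, 3.50),
                         soc_sdlog = 0.6,
                         coupling = 0.06,
                         coupling_shape = NULL,
                         noise_sd = 0.01,
                         noise_lengthscale = 50,
                         wavelengths = seq(400, 2500, by = 10)) {
  k <- nrow(centers)
  expand <- function(v, what) {
    if (length(v) == 1) rep(v, k)
    else if (length(v) == k) v
    else stop(what, " must have length 1 or ", k)
  }
  if (is.null(feature_depths)) {
    # alternating-depth absorption patterns: clusters 1/2 deep at the
    # iron-oxide (650 nm) and water (1900 nm) features, clusters 3/4 deep
    # at the hydroxyl (1400 nm) and clay (2200 nm) features, so cluster
    # identity lives in spectral shape on every region of the grid, not
    # only in overall albedo
    patterns <- matrix(c(0.45, 0.15, 0.45, 0.15,
                         0.45, 0.15, 0.45, 0.15,
                         0.15, 0.45, 0.15, 0.45,
                         0.15, 0.45, 0.15, 0.45), nrow = 4, byrow = TRUE)
    if (length(feature_centers) == 4) {
      feature_depths <- patterns[rep_len(seq_len(4), k), , drop = FALSE]
    } else {
      feature_depths <- matrix(0.2, k, length(feature_centers))
    }
  }
  if (nrow(feature_depths) != k || ncol(feature_depths) != length(feature_centers))
    stop("feature_depths must be k x length(feature_centers)")
  n_per_cluster <- expand(n_per_cluster, "n_per_cluster")
  if (any(n_per_cluster <= 0)) stop("n_per_cluster must be positive")
  if (any(c(spread, soc_sdlog, noise_sd) < 0)) stop("sds must be >= 0")
  structure(list(
    n_per_cluster = n_per_cluster, centers = centers,
    spread = expand(spread, "spread"),
    baseline = expand(baseline, "baseline"),
    baseline_slope = expand(baseline_slope, "baseline_slope"),
    feature_centers = feature_centers, feature_width = feature_width,
    feature_depths = feature_depths,
    soc_meanlog = expand(soc_meanlog, "soc_meanlog"),
    soc_sdlog = expand(soc_sdlog, "soc_sdlog"),
    coupling = expand(coupling, "coupling"),
    coupling_shape = {
      if (is.null(coupling_shape))
        # organic matter darkens soil mostly in the visible range, with a
        # weak tail into the NIR
        exp(-(wavelengths - 600)^2 / (2 * 350^2)) + 0.15
      else if (length(coupling_shape) == length(wavelengths)) coupling_shape
      else stop("coupling_shape must match the wavelength grid")
    },
    noise_sd = noise_sd, noise_lengthscale = noise_lengthscale,
    wavelengths = wavelengths
  ), class = "scene_config")
}

#' Generate a synthetic spectral scene
#'
#' Draws a reproducible spatially clustered spectral library from a
#' [scene_config()]: reflectance spectra (in (0, 1]), coordinates around
#' the cluster centres, lognormal SOC coupled negatively to reflectance,
#' and the planted ground truth (labels and soft memberships from the
#' cluster spatial densities).
#'
#' @param cfg a `scene_config`.
#' @param seed integer seed; the draw is fully determined by `cfg` + seed.
#' @return a list: `dataset` (a [spectral_dataset()] in reflectance mode
#'   with SOC target and the planted cluster as `strata`), `labels`
#'   (planted cluster per sample), `memberships` (k x n soft memberships).
#' @export
generate_scene <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(seed)
  wl <- cfg$wavelengths
  m <- length(wl)
  k <- nrow(cfg$centers)
  n <- sum(cfg$n_per_cluster)
  labels <- rep(seq_len(k), cfg$n_per_cluster)
  wl01 <- (wl - wl[1]) / (wl[m] - wl[1])
  # per-cluster endmember absorbance curves
  endmember <- sapply(seq_len(k), function(g) {
    a <- cfg$baseline[g] + cfg$baseline_slope[g] * wl01
    for (f in seq_along(cfg$feature_centers))
      a <- a + cfg$feature_depths[g, f] *
        exp(-(wl - cfg$feature_centers[f])^2 / (2 * cfg$feature_width^2))
    a
  })
  coords <- cbind(
    lon = stats::rnorm(n, cfg$centers[labels, 1], cfg$spread[labels]),
    lat = stats::rnorm(n, cfg$centers[labels, 2], cfg$spread[labels]))
  soc <- stats::rlnorm(n, cfg$soc_meanlog[labels], cfg$soc_sdlog[labels])
  # smooth correlated noise: white noise convolved with a Gaussian kernel
  noise <- matrix(0, n, m)
  if (cfg$noise_sd > 0) {
    h <- diff(wl[1:2])
    half <- ceiling(3 * cfg$noise_lengthscale / h)
    kern <- exp(-((-half:half) * h)^2 / (2 * cfg$noise_lengthscale^2))
    white <- matrix(stats::rnorm(n * (m + 2 * half)), n)
    sm <- t(apply(white, 1, function(r)
      stats::filter(r, kern, sides = 2)[(half + 1):(half + m)]))
    sm <- sm / stats::sd(as.numeric(sm))
    noise <- sm * cfg$noise_sd
  }
  absorb <- t(endmember[, labels]) +
    outer(cfg$coupling[labels] * log(soc), cfg$coupling_shape) + noise
  absorb[absorb < 0] <- 0
  refl <- 10^(-absorb)
  refl[refl > 1] <- 1
  colnames(refl) <- format(wl, trim = TRUE, scientific = FALSE)
  ds <- spectral_dataset(
    ids = sprintf("s%04d", seq_len(n)), coords = coords, wavelengths = wl,
    values = refl, target = soc,
    strata = paste0("cluster", labels), mode = "reflectance")
  # soft ground-truth memberships from the spatial mixture densities
  dens <- sapply(seq_len(k), function(g)
    stats::dnorm(coords[, 1], cfg$centers[g, 1], cfg$spread[g]) *
      stats::dnorm(coords[, 2], cfg$centers[g, 2], cfg$spread[g]))
  U <- t(dens / rowSums(dens))
  list(dataset = ds, labels = labels, memberships = U)
}

#' Named scene presets
#'
#' * `four-cluster-separated` — four well-separated spectral clusters of
#'   250 samples each; used for cluster-count recovery.
#' * `heterogeneous-slopes` — four clusters of 150 samples whose
#'   SOC-to-spectrum coupling differs strongly, so one global calibration
#'   is misspecified while per-cluster calibrations are not.
#' * `planted-band` — the response loads on a single absorption feature at
#'   1400 nm; used for band-importance recovery.
#' * `homogeneous` — a single spectral population spread over the region;
#'   used for flat bandwidth-score checks.
#'
#' @param name preset name; omit to list available presets.
#' @return a `scene_config` (or the preset names when `name` is missing).
#' @export
scene_presets <- function(name) {
  presets <- list(
    `four-cluster-separated` = function() scene_config(),
    `heterogeneous-slopes` = function()
      scene_config(n_per_cluster = 150,
                   coupling = c(0.06, 0.12, 0.18, 0.24)),
    `planted-band` = function() {
      wl <- seq(400, 2500, by = 10)
      scene_config(n_per_cluster = 300,
                   centers = matrix(c(5, 45), ncol = 2),
                   baseline = 0.4, baseline_slope = 0.25,
                   feature_depths = matrix(c(0.25, 0.15, 0.3, 0.1), 1),
                   soc_meanlog = 3.2, soc_sdlog = 0.9,
                   coupling = 0.15,
                   coupling_shape = exp(-(wl - 1400)^2 / (2 * 35^2)),
                   wavelengths = wl)
    },
    `homogeneous` = function()
      scene_config(n_per_cluster = 50,
                   centers = matrix(rep(c(5, 45), 4), ncol = 2, byrow = TRUE),
                   spread = 2.5,
                   baseline = 0.45, baseline_slope = 0.25,
                   feature_depths = matrix(rep(c(0.25, 0.12, 0.3, 0.1), 4),
                                           nrow = 4, byrow = TRUE),
                   soc_meanlog = 3.2, coupling = 0.12)
  )
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]()
}
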