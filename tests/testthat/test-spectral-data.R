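test_that("reading a wide CSV builds a validated dataset and sorts bands", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lon,lat,soc,400,410",
               "a,1.0,40.0,12.5,0.45,0.46",
               "b,1.5,40.5,30.1,0.40,0.41",
               "c,2.0,41.0,8.8,0.50,0.52"), tmp)
  ds <- read_spectra_table(tmp)
  expect_s3_class(ds, "spectral_dataset")
  expect_equal(n_samples(ds), 3)
  expect_equal(n_bands(ds), 2)
  expect_equal(ds$wavelengths, c(400, 410))
  expect_equal(ds$target, c(12.5, 30.1, 8.8))

  # shuffled wavelength columns give the same dataset
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lon,lat,soc,410,400",
               "a,1.0,40.0,12.5,0.46,0.45",
               "b,1.5,40.5,30.1,0.41,0.40",
               "c,2.0,41.0,8.8,0.52,0.50"), tmp2)
  expect_equal(read_spectra_table(tmp2)$values, ds$values)

  # round trip through write_spectra_table
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(ds, tmp3)
  expect_equal(read_spectra_table(tmp3)$values, ds$values)
})

test_that("ingestion rejects invalid tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lat,soc,400", "a,40,1,0.5"), tmp)
  expect_error(read_spectra_table(tmp), "lon")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lon,lat,soc,400,410",
               "a,1.0,40.0,12.5,1.2,0.46"), tmp2)
  expect_error(read_spectra_table(tmp2), "\\(0, 1\\]")
  expect_error(
    spectral_dataset("a", cbind(0, 0), c(410, 400), matrix(c(0.5, 0.5), 1)),
    "strictly increasing")
})

test_that("resampling to 10 nm yields 211 bands and matches the window-mean oracle", {
  wl <- seq(400, 2500, by = 0.5)
  set.seed(1)
  X <- matrix(runif(2 * length(wl), 0.2, 0.8), 2, byrow = TRUE)
  ds <- spectral_dataset(c("a", "b"), cbind(c(1, 2), c(40, 41)), wl, X)
  out <- resample_spectra(ds, 10)
  expect_equal(n_bands(out), 211)
  expect_equal(out$wavelengths, seq(400, 2500, by = 10))
  for (i in 1:2)
    expect_equal(out$values[i, ], oracle_window_mean(wl, X[i, ], 10),
                 ignore_attr = TRUE)
  # idempotence: resampling an already-coarse grid at its own interval
  out2 <- resample_spectra(out, 10)
  expect_equal(out2$values, out$values)
  expect_error(resample_spectra(out, 5), "finer")
})

test_that("absorbance transform is log10(1/R) and round-trips", {
  ds <- spectral_dataset(c("a", "b", "c"), cbind(1:3, 40:42), c(500, 600),
                         matrix(c(1, 0.1, 0.01, 1, 0.5, 0.25), 3, 2))
  ab <- to_absorbance(ds)
  expect_equal(ab$mode, "absorbance")
  expect_equal(ab$values[, 1], c(0, 1, 2), ignore_attr = TRUE)
  # inverse transform recovers reflectance to machine precision
  expect_equal(10^(-ab$values), ds$values, tolerance = 1e-12)
  expect_error(to_absorbance(ab), "absorbance mode")
})

test_that("Savitzky-Golay reproduces low-order polynomials and matches the per-window oracle", {
  wl <- seq(400, 1000, by = 10)
  quad <- 2 + 0.01 * wl - 1e-5 * wl^2
  ds <- spectral_dataset("a", cbind(1, 40), wl, matrix(quad, 1),
                         mode = "absorbance")
  sm <- savgol_smooth(ds, 15, 2)
  expect_equal(sm$values[1, ], quad, tolerance = 1e-10, ignore_attr = TRUE)

  const <- spectral_dataset("a", cbind(1, 40), wl,
                            matrix(0.37, 1, length(wl)), mode = "absorbance")
  expect_equal(savgol_smooth(const, 15, 2)$values, const$values)

  set.seed(42)
  noisy <- sin(wl / 50) + rnorm(length(wl), 0, 0.1)
  dsn <- spectral_dataset("a", cbind(1, 40), wl, matrix(noisy, 1),
                          mode = "absorbance")
  expect_equal(savgol_smooth(dsn, 15, 2)$values[1, ],
               oracle_savgol(noisy, 15, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(savgol_smooth(dsn, 14, 2), "odd")
  expect_error(savgol_smooth(dsn, 201, 2), "exceeds")
})

test_that("Savitzky-Golay smoothing is linear in the spectra", {
  wl <- seq(400, 1000, by = 10)
  set.seed(7)
  x1 <- runif(length(wl)); x2 <- runif(length(wl))
  mk <- function(x) spectral_dataset("a", cbind(1, 40), wl, matrix(x, 1),
                                     mode = "absorbance")
  f <- function(x) savgol_smooth(mk(x), 15, 2)$values[1, ]
  expect_equal(f(2 * x1 - 3 * x2), 2 * f(x1) - 3 * f(x2), tolerance = 1e-10)
})

test_that("log target transform is natural log with a drop-below-floor policy", {
  # ln of the largest SOC value reported for the published library
  expect_equal(round(log_transform_target(586.8)$log_y, 2), 6.37)
  expect_equal(log_transform_target(1)$log_y, 0)
  expect_equal(log_transform_target(exp(1))$log_y, 1)
  res <- suppressMessages(log_transform_target(c(0, 0.05, 1, 10)))
  expect_equal(res$n_dropped, 2)
  expect_equal(res$kept, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$log_y, c(0, log(10)))
  expect_error(log_transform_target(c(0, 0.01)), "floor")
})

test_that("target summary matches hand-computed moments", {
  s <- describe_target(c(1, 2, 3))
  expect_equal(s$skewness, 0)
  expect_equal(s$median, 2)

  # (0,0,0,1): mu=0.25, m2=3/16, m3=9/64... computed directly
  y <- c(0, 0, 0, 1)
  mu <- mean(y)
  m2 <- mean((y - mu)^2); m3 <- mean((y - mu)^3); m4 <- mean((y - mu)^4)
  s2 <- describe_target(y)
  expect_equal(s2$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(s2$kurtosis_raw, m4 / m2^2, tolerance = 1e-12)
  expect_equal(s2$kurtosis_excess, m4 / m2^2 - 3, tolerance = 1e-12)

  sc <- describe_target(rep(5, 10))
  expect_equal(sc$sd, 0)
  expect_true(is.nan(sc$skewness))
})

test_that("target summary agrees with the moment oracle on random vectors", {
  set.seed(11)
  for (i in 1:100) {
    y <- rlnorm(sample(5:50, 1), meanlog = 3, sdlog = 1)
    s <- describe_target(y)
    mu <- mean(y)
    m2 <- mean((y - mu)^2)
    expect_equal(s$skewness, mean((y - mu)^3) / m2^1.5, tolerance = 1e-10)
    expect_equal(s$kurtosis_excess, mean((y - mu)^4) / m2^2 - 3,
                 tolerance = 1e-10)
  }
})
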