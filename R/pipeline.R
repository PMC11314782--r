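#' Run the full spectral-classification calibration pipeline
#'
#' One reproducible run of: preprocessing (optional resampling, absorbance
#' transform, Savitzky-Golay smoothing), natural-log transform of the SOC
#' target, GWPCA (components by the eigenvalue-greater-than-one rule,
#' bisquare kernel), fuzzy c-means on the GWPCA scores (cluster count by
#' FPI/NCE sweep unless fixed), per-cluster Kennard-Stone 2:1 split and
#' calibration, and grouped evaluation. Alongside the spectral-cluster
#' report it produces the unclassified global report and, when strata
#' (e.g. land cover) are present, the stratum-wise report — all three under
#' the same validation protocol, so rows are directly comparable.
#'
#' The master seed fans out to fixed per-stage offsets so each stage is
#' individually re-runnable.
#'
#' @param ds a `spectral_dataset` in reflectance mode with SOC target.
#' @param models character vector from `c("plsr", "cubist")`.
#' @param grouping which grouped reports to produce: subset of
#'   `c("cluster", "stratum", "none")`.
#' @param resample_interval nm, `NULL` to skip resampling.
#' @param savgol_window,savgol_order Savitzky-Golay parameters.
#' @param soc_floor positivity floor for the log transform, g/kg.
#' @param k GWPCA components (`"auto"` = eigenvalue > 1 rule).
#' @param kernel a [kernel_spec()]; `NULL` selects the bandwidth by
#'   leave-one-out search (slow for large n).
#' @param c_clusters FCM cluster count, or `"auto"` for the FPI/NCE sweep.
#' @param c_range candidate counts for the sweep.
#' @param fuzziness,fcm_max_iter,fcm_tol,fcm_restarts FCM parameters.
#' @param min_group_size smallest group that gets its own model.
#' @param seed master seed.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return an object of class `pipeline_result`: `reports` (named list of
#'   `grouped_report` per grouping and model), `gwpca`, `clustering`
#'   (validity curve or fit), `dataset` (preprocessed, log target),
#'   `manifest`.
#' @export
run_pipeline <- function(ds,
                         models = c("plsr", "cubist"),
                         grouping = c("cluster", "none"),
                         resample_interval = NULL,
                         savgol_window = 15, savgol_order = 2,
                         soc_floor = 0.1,
                         k = "auto", kernel = NULL,
                         c_clusters = "auto", c_range = 2:10,
                         fuzziness = 1.5, fcm_max_iter = 300,
                         fcm_tol = 1e-3, fcm_restarts = 5,
                         min_group_size = 30,
                         seed = 1, out_dir = NULL) {
  t0 <- proc.time()[3]
  models <- match.arg(models, several.ok = TRUE)
  grouping <- match.arg(grouping, c("cluster", "stratum", "none"),
                        several.ok = TRUE)
  if (is.null(ds$target)) stop("pipeline stage 'input': dataset has no SOC target")
  stage_seed <- function(stage)
    (seed * 97L + utf8ToInt(substr(stage, 1, 1)) * 1009L) %% .Machine$integer.max

  # --- preprocessing -------------------------------------------------
  pp <- ds
  if (!is.null(resample_interval))
    pp <- resample_spectra(pp, resample_interval)
  if (pp$mode == "reflectance") pp <- to_absorbance(pp)
  pp <- savgol_smooth(pp, savgol_window, savgol_order)
  lt <- log_transform_target(pp$target, floor = soc_floor)
  if (lt$n_dropped > 0) {
    keep <- which(lt$kept)
    pp <- spectral_dataset(pp$ids[keep], pp$coords[keep, , drop = FALSE],
                           pp$wavelengths, pp$values[keep, , drop = FALSE],
                           target = pp$target[keep],
                           strata = if (is.null(pp$strata)) NULL else pp$strata[keep],
                           mode = pp$mode)
  }
  pp$target <- lt$log_y

  # --- GWPCA ---------------------------------------------------------
  gw <- NULL; clus <- NULL; labels_cluster <- NULL; chosen_c <- NA
  if ("cluster" %in% grouping) {
    gw <- fit_gwpca(pp, k = k, kernel = kernel)
    if (identical(c_clusters, "auto")) {
      clus <- sweep_clusters(gw$scores, c_range = c_range,
                             fuzziness = fuzziness, max_iter = fcm_max_iter,
                             tol = fcm_tol, seed = stage_seed("fcm"),
                             restarts = fcm_restarts)
      chosen_c <- clus$chosen_c
      fit <- clus$fits[[paste0("c", chosen_c)]]
    } else {
      chosen_c <- as.integer(c_clusters)
      fit <- fcm_fit(gw$scores, chosen_c, fuzziness = fuzziness,
                     max_iter = fcm_max_iter, tol = fcm_tol,
                     seed = stage_seed("fcm"), restarts = fcm_restarts)
      clus <- fit
    }
    labels_cluster <- paste0("cluster", fit$labels)
  }

  # --- calibration + evaluation -------------------------------------
  reports <- list()
  for (mod in models) {
    if ("cluster" %in% grouping) {
      gc <- fit_per_group(pp, labels_cluster, model = mod,
                          min_size = min_group_size)
      reports[[paste0("cluster_", mod)]] <- evaluate_grouped(gc, pp)
    }
    if ("stratum" %in% grouping) {
      if (is.null(pp$strata))
        stop("pipeline stage 'stratum': dataset has no strata")
      gc <- fit_per_group(pp, pp$strata, model = mod,
                          min_size = min_group_size)
      reports[[paste0("stratum_", mod)]] <- evaluate_grouped(gc, pp)
    }
    if ("none" %in% grouping) {
      split <- kennard_stone_split(pp$values)
      fitg <- if (mod == "plsr")
        fit_plsr(pp$values[split$cal, , drop = FALSE], pp$target[split$cal])
      else
        fit_model_tree(pp$values[split$cal, , drop = FALSE], pp$target[split$cal])
      obs <- pp$target[split$val]
      pred <- stats::predict(fitg, pp$values[split$val, , drop = FALSE])
      tab <- data.frame(group = "All", n = n_samples(pp), model = mod,
                        r2 = r2(obs, pred), rmse = rmse(obs, pred),
                        rpiq = rpiq(obs, pred))
      tab$category <- rpiq_category(tab$rpiq)
      tab$r2 <- round_half_up(tab$r2, 2)
      tab$rmse <- round_half_up(tab$rmse, 2)
      tab$rpiq <- round_half_up(tab$rpiq, 2)
      reports[[paste0("global_", mod)]] <-
        structure(list(table = tab, raw = tab), class = "grouped_report")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spectroclust")),
    seed = seed,
    n_input = n_samples(ds), n_modeled = n_samples(pp),
    n_dropped_below_floor = lt$n_dropped,
    m_bands = n_bands(pp),
    gwpca = if (is.null(gw)) NULL else list(
      k = gw$k, bandwidth = gw$kernel$bandwidth,
      adaptive = gw$kernel$adaptive, metric = gw$kernel$metric),
    chosen_c = chosen_c,
    models = models, grouping = grouping,
    wall_time_s = round(proc.time()[3] - t0, 2)
  )
  res <- structure(list(reports = reports, gwpca = gw, clustering = clus,
                        dataset = pp, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$manifest$n_modeled, " samples",
      if (!is.null(x$manifest$gwpca))
        paste0(", k=", x$manifest$gwpca$k, ", c=", x$manifest$chosen_c),
      "\n", sep = "")
  for (nm in names(x$reports)) {
    cat("\n== ", nm, " ==\n", sep = "")
    print(x$reports[[nm]])
  }
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$gwpca)) {
    sc <- data.frame(id = res$gwpca$ids, res$gwpca$scores)
    utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
    ev <- data.frame(id = res$gwpca$ids, res$gwpca$eigenvalues)
    utils::write.csv(ev, file.path(out_dir, "eigenvalues.csv"), row.names = FALSE)
  }
  if (!is.null(res$clustering)) {
    fit <- if (inherits(res$clustering, "validity_curve")) {
      utils::write.csv(res$clustering$curve,
                       file.path(out_dir, "validity_curve.csv"),
                       row.names = FALSE)
      res$clustering$fits[[paste0("c", res$clustering$chosen_c)]]
    } else res$clustering
    mem <- data.frame(id = res$gwpca$ids, t(fit$U), label = fit$labels)
    names(mem) <- c("id", paste0("mu_", seq_len(nrow(fit$U))), "label")
    utils::write.csv(mem, file.path(out_dir, "memberships.csv"),
                     row.names = FALSE)
  }
  for (nm in names(res$reports))
    utils::write.csv(res$reports[[nm]]$table,
                     file.path(out_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
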