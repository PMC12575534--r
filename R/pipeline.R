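#' Read a sub-watershed table
#'
#' CSV with columns `id`, `downstream_id` (empty for the outlet),
#' `area_cum_km2` (or `area_km2` with `areas = "incremental"`),
#' `centroid_x`, `centroid_y`, optional `excluded`, and one `ec_<season>`
#' column per sampling campaign.
#'
#' @param path CSV file path.
#' @param areas passed to [build_network()].
#' @return a `watershed_network`.
#' @export
read_subwatersheds <- function(path, areas = c("cumulative", "incremental")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("area_cum_km2" %in% names(tab)) {
    names(tab)[names(tab) == "area_cum_km2"] <- "area_km2"
  }
  build_network(tab, areas = match.arg(areas))
}

#' Scan the full model space for one season
#'
#' End-to-end analysis: computes the upstream-corrected EC response,
#' builds the design for every enumerated predictor combination, fits
#' the global OLS model and a GWR with per-model optimized bandwidth,
#' attaches Moran's I residual diagnostics for both, and applies the
#' codified selection rule.  The selected model is refitted with the
#' projection matrices retained so the coefficient-variability F test
#' and the model comparison record are available.  Deterministic: a
#' rerun with the same inputs gives identical output.
#'
#' @param network a `watershed_network` with EC observations.
#' @param landuse a `predictor_table` covering the network's nodes.
#' @param season season label to analyse.
#' @param criterion bandwidth criterion, `"cv"` or `"aicc"`.
#' @param family kernel family.
#' @param weights_scheme Moran weights scheme
#'   (see [build_weights()]).
#' @param vif_max,moran_alpha selection thresholds (see [select_best()]).
#' @param models optional list of `model_spec`s; default the full
#'   enumeration for the season.
#' @param proportions use land-use proportions instead of counts.
#' @return list of class `scan_result`: `season`, `results` (one row per
#'   model, ranked by GWR AICc), `selection`, `best` (refit of the
#'   selected model: `spec`, `global`, `gwr`, `bandwidth`, `f3`,
#'   `comparison`, `local_coefficients`), `observations`, `settings`.
#' @export
run_scan <- function(network, landuse, season,
                     criterion = c("cv", "aicc"),
                     family = c("gaussian", "bisquare"),
                     weights_scheme = c("inverse_distance", "knn"),
                     vif_max = 5, moran_alpha = 0.05,
                     models = NULL, proportions = FALSE) {
  criterion <- match.arg(criterion)
  family <- match.arg(family)
  weights_scheme <- match.arg(weights_scheme)
  stopifnot(inherits(network, "watershed_network"))

  d <- delta_ec(network, season)
  obs <- d$id[d$provenance != "unavailable"]
  y <- d$delta_ec[match(obs, d$id)]
  coords <- as.matrix(network$nodes[match(obs, network$nodes$id),
                                    c("centroid_x", "centroid_y")])
  rownames(coords) <- obs
  weights <- build_weights(coords, scheme = weights_scheme)
  if (is.null(models)) models <- enumerate_models(season)

  fit_one <- function(spec) {
    row <- data.frame(
      predictors = paste(spec$predictors, collapse = "+"),
      n = length(obs), n_predictors = length(spec$predictors),
      aic = NA_real_, aicc = NA_real_, bic = NA_real_,
      adj_r_squared = NA_real_, max_vif = NA_real_,
      bandwidth = NA_real_, gwr_aicc = NA_real_,
      gwr_adj_r_squared = NA_real_,
      glm_moran_I = NA_real_, glm_moran_p = NA_real_,
      gwr_moran_I = NA_real_, gwr_moran_p = NA_real_,
      error = NA_character_, stringsAsFactors = FALSE
    )
    tryCatch({
      X <- predictor_matrix(landuse, spec$predictors, ids = obs,
                            proportions = proportions)
      global <- fit_ols(X, y)
      row$aic <- global$aic; row$aicc <- global$aicc; row$bic <- global$bic
      row$adj_r_squared <- global$adj_r_squared
      row$max_vif <- if (all(is.na(global$vif))) NA_real_ else max(global$vif)
      m_glm <- morans_i(global$residuals, weights)
      row$glm_moran_I <- m_glm$I; row$glm_moran_p <- m_glm$p_value

      bw <- optimize_bandwidth(X, y, coords, family = family,
                               criterion = criterion)
      gwr <- fit_gwr(X, y, coords, bw$bandwidth, family = family,
                     keep_projection = FALSE)
      row$bandwidth <- bw$bandwidth
      row$gwr_aicc <- gwr$aicc
      row$gwr_adj_r_squared <- gwr$adj_r_squared
      m_gwr <- morans_i(gwr$residuals, weights)
      row$gwr_moran_I <- m_gwr$I; row$gwr_moran_p <- m_gwr$p_value
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
  }

  results <- do.call(rbind, lapply(models, fit_one))
  selection <- select_best(results, vif_max = vif_max,
                           moran_alpha = moran_alpha)

  best <- NULL
  if (!selection$no_admissible) {
    preds <- strsplit(selection$selected$predictors, "+", fixed = TRUE)[[1L]]
    X <- predictor_matrix(landuse, preds, ids = obs,
                          proportions = proportions)
    global <- fit_ols(X, y)
    bw <- optimize_bandwidth(X, y, coords, family = family,
                             criterion = criterion)
    gwr <- fit_gwr(X, y, coords, bw$bandwidth, family = family,
                   keep_projection = TRUE)
    best <- list(
      spec = model_spec(season, preds),
      global = global, gwr = gwr, bandwidth = bw,
      f3 = f3_test(gwr, global),
      comparison = compare_models(global, gwr, weights),
      local_coefficients = data.frame(
        id = obs, x = coords[, 1L], y = coords[, 2L], gwr$beta,
        check.names = FALSE, stringsAsFactors = FALSE
      )
    )
  }

  structure(
    list(
      season = season,
      results = rank_models(results, "gwr_aicc"),
      selection = selection,
      best = best,
      observations = data.frame(id = obs, delta_ec = y, coords,
                                stringsAsFactors = FALSE),
      settings = list(criterion = criterion, family = family,
                      weights_scheme = weights_scheme,
                      vif_max = vif_max, moran_alpha = moran_alpha,
                      proportions = proportions,
                      n_models = length(models))
    ),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Model scan, season '", x$season, "': ", x$settings$n_models,
      " models over ", nrow(x$observations), " observations\n", sep = "")
  print(x$selection)
  if (!is.null(x$best)) {
    cat("\nSelected model comparison:\n")
    print(x$best$comparison, row.names = FALSE)
    cat("\nBandwidth: ")
    print(x$best$bandwidth)
    cat("\nCoefficient nonstationarity (F3):\n")
    print(x$best$f3, row.names = FALSE)
  }
  invisible(x)
}

#' Write scan outputs to a directory
#'
#' Emits `models_<season>.csv` (one row per enumerated model),
#' `local_coefficients_<season>.csv` (per-node local estimates of the
#' selected model), `selection_<season>.txt` (the selection-rule trace)
#' and `run_metadata_<season>.json` (settings echo for provenance).
#'
#' @param scan a `scan_result`.
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_scan_results <- function(scan, dir) {
  stopifnot(inherits(scan, "scan_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  season <- scan$season
  paths <- c(
    models = file.path(dir, paste0("models_", season, ".csv")),
    coefs = file.path(dir, paste0("local_coefficients_", season, ".csv")),
    selection = file.path(dir, paste0("selection_", season, ".txt")),
    metadata = file.path(dir, paste0("run_metadata_", season, ".json"))
  )
  utils::write.csv(scan$results, paths[["models"]], row.names = FALSE)
  if (!is.null(scan$best)) {
    utils::write.csv(scan$best$local_coefficients, paths[["coefs"]],
                     row.names = FALSE)
  }
  con <- file(paths[["selection"]], "w")
  sink(con)
  print(scan$selection)
  if (nrow(scan$selection$filtered) > 0L) {
    cat("\nFiltered models:\n")
    print(scan$selection$filtered[, c("predictors", "reason")],
          row.names = FALSE)
  }
  sink()
  close(con)
  jsonlite::write_json(
    c(list(season = season,
           package_version = as.character(utils::packageVersion("gwrshed"))),
      scan$settings),
    paths[["metadata"]], auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
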