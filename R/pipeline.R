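#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end run: synthetic campaign
#' and scene generation, radiometric correction, matchup construction,
#' exhaustive index calibration, thematic mapping, and the
#' registry-vs-recalibration comparison.
#'
#' @param seed Master seed; every stochastic stage derives from it.
#' @param n_samples Field samples in the synthetic campaign.
#' @param noise_cv Reflectance noise (coefficient of variation) for the
#'   synthetic matchup spectra and scene.
#' @param scene_shape `c(rows, cols)` of the simulated scene.
#' @param water_fraction Water proportion of the scene.
#' @param max_lag_days Matchup time window (days).
#' @param k_folds Cross-validation folds.
#' @param mask_threshold NIR water-mask reflectance threshold.
#' @param variables Variables to calibrate and map.
#' @param families Fit families for the index search.
#' @param top_n Rows kept in each ranked table.
#' @param registry_sensor Registry models used for mapping/comparison.
#' @param stages Character subset of
#'   `c("simulate","calibrate","map","compare")` to run.
#' @param out_dir Optional output directory; tables are written there.
#' @return A `wq_pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_samples = 200, noise_cv = 0.05,
                            scene_shape = c(100L, 100L),
                            water_fraction = 0.8,
                            max_lag_days = 3, k_folds = 10,
                            mask_threshold = 0.2,
                            variables = c("chl_a", "sdd", "tsm", "pim",
                                          "pom"),
                            families = c("linear", "exponential", "power",
                                         "logarithmic", "polynomial"),
                            top_n = 5,
                            registry_sensor = "PeruSAT-1",
                            stages = c("simulate", "calibrate", "map",
                                       "compare"),
                            out_dir = NULL) {
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         noise_cv = noise_cv, scene_shape = as.integer(scene_shape),
         water_fraction = water_fraction,
         max_lag_days = max_lag_days, k_folds = as.integer(k_folds),
         mask_threshold = mask_threshold, variables = variables,
         families = families, top_n = top_n,
         registry_sensor = registry_sensor, stages = stages,
         out_dir = out_dir),
    class = "wq_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys take
#' the defaults.
#' @param path YAML file path.
#' @return A `wq_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

run_stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full retrieval pipeline
#'
#' Sequences the stages on synthetic inputs: (1) `simulate` a field
#' campaign and a DN-level scene; (2) build the calibration database by
#' synthesizing a matchup spectrum per sample with the bio-optical
#' forward model; (3) `calibrate`: exhaustive two-band index search with
#' k-fold cross-validation per variable; (4) `map`: radiometric
#' correction of the scene, water masking, and one thematic map per
#' registry model; (5) `compare`: the freshly calibrated best model
#' versus the published registry model on the matchup points.
#' Everything derives from the master seed, so two runs with the same
#' configuration are identical.
#'
#' @param config A `wq_pipeline_config`.
#' @return A run report: list with `samples`, `matchup_table`,
#'   `rankings` (per variable), `maps` (per variable), `comparison`,
#'   `counts`, `reproducibility` (`seed`, `config_hash`), and
#'   `manifest` (files written, possibly empty).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "wq_pipeline_config"))
  manifest <- character(0)
  report <- list(reproducibility = list(seed = config$seed,
                                        config_hash = config_hash(config)))

  # -- simulate ------------------------------------------------------
  sim_cfg <- sim_config(n_samples = config$n_samples, seed = config$seed,
                        noise_cv = config$noise_cv,
                        scene_shape = config$scene_shape,
                        water_fraction = config$water_fraction)
  samples <- run_stage("simulate", simulate_field_campaign(sim_cfg))
  sim <- if ("map" %in% config$stages) {
    run_stage("simulate", simulate_scene(sim_cfg))
  } else NULL
  report$samples <- samples

  # calibration database: one synthetic matchup spectrum per sample
  matchup_table <- run_stage("simulate", {
    spectra <- t(vapply(seq_len(nrow(samples)), function(i) {
      bio_optical_forward(samples[i, ], noise_cv = config$noise_cv,
                          seed = config$seed + i)
    }, numeric(4)))
    colnames(spectra) <- c("B1", "B2", "B3", "B4")
    tibble::tibble(point_id = samples$point_id,
                   image_date = samples$campaign_date,
                   sample_date = samples$campaign_date,
                   lag_days = 0L,
                   as.data.frame(spectra),
                   samples[, intersect(.wq_variables, names(samples))])
  })
  report$matchup_table <- matchup_table

  # -- calibrate -----------------------------------------------------
  if ("calibrate" %in% config$stages) {
    report$rankings <- run_stage("calibrate", {
      out <- list()
      for (v in config$variables) {
        out[[v]] <- rank_indices(matchup_table, v,
                                 families = config$families,
                                 k = config$k_folds, seed = config$seed,
                                 top_n = config$top_n)
      }
      out
    })
  }

  # -- map -----------------------------------------------------------
  if ("map" %in% config$stages) {
    report$maps <- run_stage("map", {
      scn <- dn_to_radiance(sim$scene, sim$calibration)
      scn <- invert_surface_reflectance(scn, sim$atmosphere)
      mask <- water_mask(scn, config$mask_threshold)
      registry <- published_registry(config$registry_sensor)
      maps <- list()
      for (v in config$variables) {
        key <- paste0(config$registry_sensor, ".", v)
        if (!key %in% names(registry)) next
        maps[[v]] <- apply_model(scn, registry[[key]], mask)
      }
      maps
    })
  }

  # -- compare -------------------------------------------------------
  if ("compare" %in% config$stages && "calibrate" %in% config$stages) {
    report$comparison <- run_stage("compare", {
      registry <- published_registry(config$registry_sensor)
      rows <- list()
      for (v in config$variables) {
        key <- paste0(config$registry_sensor, ".", v)
        if (!key %in% names(registry)) next
        best <- report$rankings[[v]]$top$fit[[1]]
        x <- suppressWarnings(compute_index(matchup_table, best$index))
        pred_new <- best$predict(x)
        pred_reg <- predict_retrieval(registry[[key]],
                                      spectrum = matchup_table)
        rows[[v]] <- compare_sensors(pred_new, pred_reg, matchup_table,
                                     variable = v,
                                     sensors = c("recalibrated",
                                                 "registry"))
      }
      do.call(rbind, rows)
    })
  }

  report$counts <- list(
    n_samples = nrow(samples),
    n_matchups = nrow(matchup_table),
    n_water_pixels = if (!is.null(sim)) sum(sim$water_mask) else NA_integer_
  )

  # -- write outputs -------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(config$out_dir, "field_samples.csv")
    write_field_samples(samples, f); manifest <- c(manifest, f)
    f <- file.path(config$out_dir, "matchups.csv")
    utils::write.csv(matchup_table, f, row.names = FALSE)
    manifest <- c(manifest, f)
    for (v in names(report$rankings)) {
      f <- file.path(config$out_dir, paste0("ranking_", v, ".csv"))
      write_ranking_csv(report$rankings[[v]], f)
      manifest <- c(manifest, f)
    }
    if (!is.null(report$comparison)) {
      f <- file.path(config$out_dir, "sensor_comparison.csv")
      utils::write.csv(report$comparison, f, row.names = FALSE)
      manifest <- c(manifest, f)
    }
    f <- file.path(config$out_dir, "registry.json")
    write_registry_json(published_registry("all"), f)
    manifest <- c(manifest, f)
  }
  report$manifest <- manifest
  class(report) <- "wq_run_report"
  report
}

#' @export
print.wq_run_report <- function(x, ...) {
  cat("<wq_run_report> seed ", x$reproducibility$seed,
      ", config ", x$reproducibility$config_hash, "\n",
      "  samples: ", x$counts$n_samples,
      ", matchups: ", x$counts$n_matchups, "\n", sep = "")
  for (v in names(x$rankings)) {
    top <- x$rankings[[v]]$top
    cat(sprintf("  %-5s best: %s %s (CV RMSE %.4g)\n", v,
                top$band_comb[1], top$family[1], top$rmse[1]))
  }
  invisible(x)
}
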