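default_output_range <- function(obs_range, variable) {
  # observed range with 50% headroom above the max, floored at zero
  # (transparency floored at 1 cm): thematic palettes are bounded
  lo <- if (variable == "sdd") 0.01 else 0
  c(lo, obs_range[2] * 1.5)
}

#' Registry of published retrieval models
#'
#' The calibrated best-per-variable algorithms for the four-band
#' high-resolution sensor (linear fits on two-band indices: Chl-a and SDD
#' on (B4-B1)/(B4+B1), TSM on B1/B4, PIM on (B3-B1)/(B3+B1), POM on
#' B3/B4) and the literature Sentinel-2 models used for the sensor
#' comparison (six-band spectra named R490..R783, including the
#' three-band Chl-a model).
#'
#' @param sensor `"PeruSAT-1"`, `"Sentinel-2"`, or `"all"` (default).
#' @return Named list of `wq_retrieval_model` objects, keyed
#'   `<sensor>.<variable>`.
#' @examples
#' m <- published_registry("PeruSAT-1")$`PeruSAT-1.chl_a`
#' predict_retrieval(m, index_value = 0)  # 198.95
#' @export
published_registry <- function(sensor = c("all", "PeruSAT-1", "Sentinel-2")) {
  sensor <- match.arg(sensor)
  out <- list()
  if (sensor %in% c("all", "PeruSAT-1")) {
    for (v in names(.pub_perusat)) {
      p <- .pub_perusat[[v]]
      out[[paste0("PeruSAT-1.", v)]] <- structure(
        list(sensor = "PeruSAT-1", variable = p$variable, units = p$units,
             type = "index_linear",
             index = index_spec(p$index$family, p$index$a, p$index$b),
             slope = p$slope, intercept = p$intercept,
             formula = fit_formula_string(
               "linear", c(slope = p$slope, intercept = p$intercept)),
             obs_range = p$obs_range,
             obs_range_printed = if (!is.null(p$obs_range_printed))
               p$obs_range_printed else p$obs_range,
             valid_output_range = default_output_range(p$obs_range, v),
             provenance = "calibrated four-band best algorithm"),
        class = "wq_retrieval_model")
    }
  }
  if (sensor %in% c("all", "Sentinel-2")) {
    for (v in names(.pub_sentinel2)) {
      p <- .pub_sentinel2[[v]]
      obs <- .pub_perusat[[v]]$obs_range
      out[[paste0("Sentinel-2.", v)]] <- structure(
        list(sensor = "Sentinel-2", variable = p$variable, units = p$units,
             type = "spectrum_formula", fun = p$fun, formula = p$formula,
             obs_range = obs,
             valid_output_range = default_output_range(obs, v),
             provenance = "published Sentinel-2 literature model"),
        class = "wq_retrieval_model")
    }
  }
  out
}

#' @export
print.wq_retrieval_model <- function(x, ...) {
  cat("<wq_retrieval_model> ", x$sensor, " ", x$variable, " (", x$units,
      "): ", x$formula,
      if (x$type == "index_linear") paste0(" on ", index_name(x$index)),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a retrieval model
#'
#' Index-based models accept either a precomputed index value or a named
#' reflectance spectrum (the index is computed first); spectrum-formula
#' models (Sentinel-2) require a named spectrum.
#'
#' @param model A `wq_retrieval_model`.
#' @param index_value Numeric index value(s) (index-based models only).
#' @param spectrum Named reflectance vector / matrix with band columns.
#' @return Predicted value(s) in the model's units (not clamped).
#' @export
predict_retrieval <- function(model, index_value = NULL, spectrum = NULL) {
  if (model$type == "index_linear") {
    if (is.null(index_value)) {
      if (is.null(spectrum)) stop("supply index_value or spectrum")
      index_value <- compute_index(spectrum, model$index)
    }
    model$slope * index_value + model$intercept
  } else {
    if (is.null(spectrum)) stop("spectrum-formula models need a spectrum")
    model$fun(spectrum)
  }
}

#' NIR-threshold water mask
#'
#' Water is detected by its low near-infrared reflectance: a pixel is
#' water iff its B4 (NIR) reflectance is below the threshold. The
#' default 0.2 separates even hypertrophic (NIR-bright) water from
#' vegetated land.
#'
#' @param scn A `wq_scene` in `surface_reflectance` state.
#' @param nir_threshold Reflectance threshold (default 0.2).
#' @param band NIR band label (default `"B4"`).
#' @return Logical matrix, TRUE = water. Warns if no pixel is water.
#' @export
water_mask <- function(scn, nir_threshold = 0.2, band = "B4") {
  assert_state(scn, "surface_reflectance")
  nir <- scene_band(scn, band)
  mask <- !is.na(nir) & nir < nir_threshold
  if (!any(mask)) warning("water mask is empty: no pixel below threshold")
  mask
}

#' Apply a retrieval model to a masked reflectance scene
#'
#' Computes the model's spectral index per water pixel, evaluates the
#' model, and clamps the output to its valid range (clamp counts are
#' recorded); non-water and invalid (zero-denominator) pixels carry
#' nodata.
#'
#' @param scn A `wq_scene` in `surface_reflectance` state.
#' @param model A `wq_retrieval_model` evaluable on the scene's bands.
#' @param mask Logical water mask (default computed by [water_mask()]).
#' @return A `wq_thematic_map`: list with `raster` (matrix, NA outside
#'   water), `variable`, `units`, `date`, `counts` (named: `masked`,
#'   `invalid`, `clamped_low`, `clamped_high`, `in_range`), `model`,
#'   `mask_provenance`.
#' @export
apply_model <- function(scn, model, mask = water_mask(scn)) {
  assert_state(scn, "surface_reflectance")
  if (model$type != "index_linear") {
    stop("only index-based models can be applied to a 4-band scene")
  }
  d <- dim(scn$data)
  if (!all(dim(mask) == d[1:2])) stop("mask dimensions do not match scene")
  if (!any(mask)) stop("empty water mask: nothing to map")
  ra <- scene_band(scn, model$index$a)
  rb <- scene_band(scn, model$index$b)
  idx <- if (model$index$family == "SR") {
    den <- rb; num <- ra
    den[den == 0] <- NA
    num / den
  } else {
    den <- ra + rb
    den[den == 0] <- NA
    (ra - rb) / den
  }
  pred <- model$slope * idx + model$intercept
  pred[!mask] <- NA
  invalid <- mask & is.na(pred)
  rng <- model$valid_output_range
  low <- !is.na(pred) & pred < rng[1]
  high <- !is.na(pred) & pred > rng[2]
  pred[low] <- rng[1]
  pred[high] <- rng[2]
  counts <- c(masked = sum(!mask), invalid = sum(invalid),
              clamped_low = sum(low), clamped_high = sum(high),
              in_range = sum(!is.na(pred)) - sum(low) - sum(high))
  structure(
    list(raster = pred, variable = model$variable, units = model$units,
         date = scn$date, counts = counts, model = model,
         mask_provenance = "NIR threshold water mask"),
    class = "wq_thematic_map"
  )
}

#' @export
print.wq_thematic_map <- function(x, ...) {
  cat("<wq_thematic_map> ", x$variable, " (", x$units, ")",
      if (!is.null(x$date)) paste0(", ", x$date),
      "; pixels in range: ", x$counts[["in_range"]],
      ", clamped: ", x$counts[["clamped_low"]] + x$counts[["clamped_high"]],
      "\n", sep = "")
  invisible(x)
}

#' Side-by-side validation statistics for two sensors
#'
#' Tabulates [summary_stats()] of each sensor's predictions against the
#' field values for one variable, the standard sensor-intercomparison
#' table.
#'
#' @param predictions_a,predictions_b Predicted values at the common
#'   points.
#' @param field Field samples (data frame with the variable column), or
#'   a numeric vector of observed values.
#' @param variable Variable name (used to pull the column and label the
#'   rows).
#' @param sensors Length-2 character labels for the two sensors.
#' @return Tibble with columns `parameter`, `sensor`, `r_squared`,
#'   `rmse`, `nrmse_pct`, `mae`, `bias`, `n`.
#' @export
compare_sensors <- function(predictions_a, predictions_b, field,
                            variable = "chl_a",
                            sensors = c("A", "B")) {
  obs <- if (is.numeric(field)) field else field[[variable]]
  if (is.null(obs)) stop("field data lack variable ", variable)
  ok <- is.finite(obs) & is.finite(predictions_a) & is.finite(predictions_b)
  if (sum(ok) < 2) stop("fewer than 2 common points")
  sa <- summary_stats(obs[ok], predictions_a[ok])
  sb <- summary_stats(obs[ok], predictions_b[ok])
  out <- rbind(sa, sb)
  tibble::tibble(parameter = variable, sensor = sensors, out)
}

season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Seasonal series of thematic maps
#'
#' Applies one retrieval model to a dated scene collection and returns
#' the maps labelled by meteorological season (DJF winter, MAM spring,
#' JJA summer, SON autumn), ordered winter -> spring -> summer -> autumn
#' and by date within a season.
#'
#' @param scenes List of dated `wq_scene` objects in
#'   `surface_reflectance` state.
#' @param model A `wq_retrieval_model`.
#' @param nir_threshold Water-mask threshold passed to [water_mask()].
#' @return List of `wq_thematic_map` objects, each with a `season`
#'   element, in seasonal order.
#' @export
seasonal_map_series <- function(scenes, model, nir_threshold = 0.2) {
  if (length(scenes) == 0) stop("need at least one scene")
  maps <- lapply(scenes, function(s) {
    m <- apply_model(s, model, water_mask(s, nir_threshold))
    m$season <- season_of(s$date)
    m
  })
  seasons <- vapply(maps, function(m) m$season, character(1))
  dates <- as.Date(vapply(maps, function(m) as.character(m$date),
                          character(1)))
  ord <- order(match(seasons, c("winter", "spring", "summer", "autumn")),
               dates)
  maps[ord]
}
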