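# Tabular and raster interchange. Field tables travel as CSV with the
# fixed header used throughout the project; scenes as multi-band float
# TIFF (band order B1..B4) with a JSON sidecar carrying state,
# geotransform, CRS and date; calibration/atmosphere as YAML keyed by
# band label.

.sample_csv_cols <- c(point_id = "point_id", date = "campaign_date",
                      chl_a_ug_L = "chl_a", sdd_m = "sdd",
                      tsm_mg_L = "tsm", pim_mg_L = "pim", pom_mg_L = "pom")

#' Write / read field-sample tables
#'
#' CSV with header
#' `point_id,date,chl_a_ug_L,sdd_m,tsm_mg_L,pim_mg_L,pom_mg_L`.
#'
#' @param samples A `wq_field_samples` tibble.
#' @param path File path.
#' @return `read_field_samples` returns a `wq_field_samples` tibble.
#' @export
write_field_samples <- function(samples, path) {
  out <- data.frame(
    point_id = samples$point_id,
    date = as.character(samples$campaign_date),
    chl_a_ug_L = samples$chl_a, sdd_m = samples$sdd,
    tsm_mg_L = samples$tsm, pim_mg_L = samples$pim,
    pom_mg_L = samples$pom, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_samples
#' @export
read_field_samples <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.sample_csv_cols), names(raw))
  if (length(missing_cols)) {
    stop("sample CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    point_id = as.character(raw$point_id),
    campaign_date = as.Date(raw$date),
    chl_a = as.numeric(raw$chl_a_ug_L), sdd = as.numeric(raw$sdd_m),
    tsm = as.numeric(raw$tsm_mg_L), pim = as.numeric(raw$pim_mg_L),
    pom = as.numeric(raw$pom_mg_L))
  complete <- !is.na(out$tsm) & !is.na(out$pim) & !is.na(out$pom)
  bad <- complete & abs(out$tsm - out$pim - out$pom) > 1e-9
  if (any(bad)) {
    stop("TSM = PIM + POM violated for point(s): ",
         paste(out$point_id[bad], collapse = ", "))
  }
  class(out) <- c("wq_field_samples", class(out))
  out
}

#' Read a hyperspectral Rrs spectrum
#'
#' Two-column CSV `wavelength_nm, Rrs` (any second-column name accepted).
#'
#' @param path File path.
#' @return Data frame with `wavelength_nm` and `rrs`.
#' @export
read_spectrum_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("spectrum CSV needs two columns")
  data.frame(wavelength_nm = as.numeric(raw[[1]]),
             rrs = as.numeric(raw[[2]]))
}

#' Read per-band calibration or atmospheric terms from YAML
#'
#' Calibration YAML: top-level optional `convention`, then one mapping
#' per band label with `gain` and `bias`. Atmosphere YAML: one mapping
#' per band with `L0`, `I0`, `Tg`, `Tud`, `S`.
#'
#' @param path File path.
#' @return A [radiometric_calibration()] / [atmospheric_terms()] object.
#' @export
read_calibration_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  convention <- if (!is.null(y$convention)) y$convention else "divide"
  y$convention <- NULL
  labs <- names(y)
  radiometric_calibration(
    gain = vapply(y, function(b) as.numeric(b$gain), numeric(1)),
    bias = vapply(y, function(b) as.numeric(b$bias %||% 0), numeric(1)),
    convention = convention, labels = labs)
}

#' @rdname read_calibration_yaml
#' @export
read_atmosphere_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  labs <- names(y)
  g <- function(f) vapply(y, function(b) as.numeric(b[[f]]), numeric(1))
  atmospheric_terms(L0 = g("L0"), I0 = g("I0"), Tg = g("Tg"),
                    Tud = g("Tud"), S = g("S"), labels = labs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a scene as multi-band TIFF with JSON sidecar
#'
#' Pixel data are stored as 32-bit float TIFF samples (band order as in
#' the band set); scene state, band labels, geotransform, CRS, date and
#' nodata go to `<path>.json`. DN scenes are scaled by the bit depth on
#' write and restored on read. Requires the `tiff` package.
#'
#' @param scn A `wq_scene`.
#' @param path TIFF file path.
#' @param bit_depth DN bit depth used to scale DN scenes into [0, 1]
#'   for storage (default 12).
#' @return `read_scene_tiff` returns a `wq_scene`.
#' @export
write_scene_tiff <- function(scn, path, bit_depth = 12) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for raster I/O")
  }
  scale <- if (scn$state == "DN") 2^bit_depth - 1 else 1
  d <- dim(scn$data)
  img <- scn$data / scale
  tiff::writeTIFF(lapply(seq_len(d[3]), function(b) img[, , b]),
                  path, bits.per.sample = 32L)
  meta <- list(state = scn$state, bands = scn$band_set$label,
               wl_min_nm = scn$band_set$wl_min_nm,
               wl_max_nm = scn$band_set$wl_max_nm,
               resolution_m = scn$band_set$resolution_m[1],
               geotransform = scn$geotransform, crs = scn$crs,
               date = if (is.null(scn$date)) NULL else as.character(scn$date),
               scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for raster I/O")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  arr <- array(NA_real_, c(dim(planes[[1]])[1:2], length(planes)))
  for (b in seq_along(planes)) arr[, , b] <- planes[[b]] * meta$scale
  if (meta$state == "DN") arr <- round(arr)
  scene(arr, state = meta$state,
        band_set = band_set(labels = meta$bands, wl_min = meta$wl_min_nm,
                            wl_max = meta$wl_max_nm,
                            resolution_m = meta$resolution_m),
        date = meta$date, geotransform = meta$geotransform, crs = meta$crs)
}

#' Write a ranked-algorithm table as CSV
#'
#' Columns mirror the published best-algorithm tables:
#' `band_comb,formula,r2,rmse,nrmse_pct,mae,bias` (plus `family` and
#' `n`).
#'
#' @param ranking A `wq_ranking` from [rank_indices()].
#' @param path File path.
#' @param top_only Write only the top rows (default TRUE).
#' @export
write_ranking_csv <- function(ranking, path, top_only = TRUE) {
  tab <- if (top_only) ranking$top else ranking$table
  utils::write.csv(
    tab[, c("band_comb", "family", "formula", "r2", "rmse", "nrmse_pct",
            "mae", "bias", "n")],
    path, row.names = FALSE)
  invisible(path)
}

#' Serialize the model registry to JSON
#'
#' @param registry Output of [published_registry()].
#' @param path File path.
#' @export
write_registry_json <- function(registry, path) {
  ser <- lapply(registry, function(m) {
    out <- list(sensor = m$sensor, variable = m$variable, units = m$units,
                type = m$type, formula = m$formula,
                obs_range = m$obs_range,
                valid_output_range = m$valid_output_range,
                provenance = m$provenance)
    if (m$type == "index_linear") {
      out$index <- index_name(m$index)
      out$slope <- m$slope
      out$intercept <- m$intercept
    }
    out
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
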