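#' Radiometric calibration coefficients
#'
#' Per-band gain and bias used to convert raw digital numbers (DN) to
#' top-of-atmosphere (TOA) radiance. Two conventions are supported because
#' product documentation is ambiguous between them:
#' `divide` (L = DN / gain + bias, the Airbus/NAOMI product convention,
#' the default) and `multiply` (L = DN * gain + bias).
#'
#' @param gain Positive numeric vector, one value per band.
#' @param bias Numeric vector, one value per band (radiance offset).
#' @param convention `"divide"` or `"multiply"`.
#' @param labels Band labels the coefficients refer to.
#'
#' @return A `wq_calibration` object (list with `gain`, `bias`,
#'   `convention`, `labels`).
#' @export
radiometric_calibration <- function(gain, bias = rep(0, length(gain)),
                                    convention = c("divide", "multiply"),
                                    labels = paste0("B", seq_along(gain))) {
  convention <- match.arg(convention)
  gain <- as.numeric(gain)
  bias <- as.numeric(bias)
  if (length(bias) != length(gain)) stop("gain and bias lengths differ")
  if (any(!is.finite(gain)) || any(gain <= 0)) {
    stop("all gains must be finite and > 0")
  }
  structure(
    list(gain = gain, bias = bias, convention = convention,
         labels = as.character(labels)),
    class = "wq_calibration"
  )
}

#' Atmospheric terms for the Lambertian TOA radiance model
#'
#' Per-band terms of the Lambertian coupling between surface reflectance
#' rho and TOA radiance:
#' \deqn{L = L_0 + \frac{I_0 T_g T_{ud}}{\pi}\,\frac{\rho}{1 - S\rho}}
#' where `L0` is the atmospheric path radiance, `I0` the band effective
#' solar irradiance (already scaled by Earth-Sun distance and solar zenith
#' cosine), `Tg` the gaseous transmittance, `Tud` the two-way (down times
#' up) scattering transmittance and `S` the atmospheric spherical albedo.
#' These terms come from a radiative transfer code run for the acquisition
#' conditions; here they are pipeline inputs.
#'
#' @param L0 Path radiance per band (>= 0), radiance units.
#' @param I0 Effective solar irradiance term per band (> 0).
#' @param Tg Gaseous transmittance per band, in (0, 1].
#' @param Tud Two-way scattering transmittance per band, in (0, 1].
#' @param S Spherical albedo per band, in [0, 1).
#' @param labels Band labels.
#'
#' @return A `wq_atmosphere` object.
#' @export
atmospheric_terms <- function(L0, I0, Tg, Tud, S,
                              labels = paste0("B", seq_along(L0))) {
  n <- length(L0)
  stopifnot(length(I0) == n, length(Tg) == n, length(Tud) == n,
            length(S) == n)
  if (any(L0 < 0)) stop("path radiance L0 must be >= 0")
  if (any(I0 <= 0)) stop("solar irradiance term I0 must be > 0")
  if (any(Tg <= 0 | Tg > 1)) stop("Tg must lie in (0, 1]")
  if (any(Tud <= 0 | Tud > 1)) stop("Tud must lie in (0, 1]")
  if (any(S < 0 | S >= 1)) stop("spherical albedo S must lie in [0, 1)")
  structure(
    list(L0 = as.numeric(L0), I0 = as.numeric(I0), Tg = as.numeric(Tg),
         Tud = as.numeric(Tud), S = as.numeric(S),
         labels = as.character(labels)),
    class = "wq_atmosphere"
  )
}

# direct-beam transfer factor I0*Tg*Tud/pi per band
atm_k <- function(terms) terms$I0 * terms$Tg * terms$Tud / pi

#' Construct a scene
#'
#' A scene is a rows x cols x bands pixel array in one of three states:
#' raw digital numbers (`DN`), TOA radiance (`TOA_radiance`) or surface
#' reflectance (`surface_reflectance`). State transitions are one-way:
#' DN -> TOA_radiance -> surface_reflectance.
#'
#' @param data Numeric array `rows x cols x n_bands`.
#' @param state One of `"DN"`, `"TOA_radiance"`, `"surface_reflectance"`.
#' @param band_set A [band_set()].
#' @param date Acquisition date (`Date` or coercible), optional.
#' @param geotransform Numeric length-6 affine geotransform
#'   (x0, dx, rx, y0, ry, dy); defaults to a unit pixel grid.
#' @param crs CRS description string (free form).
#' @param nodata Sentinel value marking missing pixels.
#'
#' @return A `wq_scene` object.
#' @export
scene <- function(data, state = c("DN", "TOA_radiance", "surface_reflectance"),
                  band_set = lagoonwq::band_set(), date = NULL,
                  geotransform = c(0, 1, 0, 0, 0, -1), crs = "local",
                  nodata = NA_real_) {
  state <- match.arg(state)
  if (length(dim(data)) != 3) stop("scene data must be a 3-d array")
  if (dim(data)[3] != n_bands(band_set)) {
    stop("third dimension of data (", dim(data)[3],
         ") does not match band set (", n_bands(band_set), " bands)")
  }
  structure(
    list(data = data, state = state, band_set = band_set,
         date = if (is.null(date)) NULL else as.Date(date),
         geotransform = geotransform, crs = crs, nodata = nodata,
         flags = list()),
    class = "wq_scene"
  )
}

#' @export
print.wq_scene <- function(x, ...) {
  d <- dim(x$data)
  cat("<wq_scene> ", d[1], " x ", d[2], " pixels, ", d[3], " bands, state: ",
      x$state, if (!is.null(x$date)) paste0(", date: ", x$date), "\n",
      sep = "")
  invisible(x)
}

scene_band <- function(scene, label) {
  scene$data[, , band_index(scene$band_set, label)]
}

assert_state <- function(scene, state) {
  if (!inherits(scene, "wq_scene")) stop("not a wq_scene")
  if (scene$state != state) {
    stop("scene is in state '", scene$state, "', expected '", state, "'")
  }
  invisible(scene)
}

#' Convert digital numbers to TOA radiance
#'
#' Applies the per-band affine radiometric calibration. Under the
#' `divide` convention L = DN / gain + bias; under `multiply`
#' L = DN * gain + bias. Nodata pixels propagate.
#'
#' @param scn A `wq_scene` in `DN` state.
#' @param calibration A [radiometric_calibration()].
#' @return The scene in `TOA_radiance` state.
#' @export
dn_to_radiance <- function(scn, calibration) {
  assert_state(scn, "DN")
  stopifnot(inherits(calibration, "wq_calibration"))
  nb <- n_bands(scn$band_set)
  if (length(calibration$gain) != nb) {
    stop("calibration has ", length(calibration$gain),
         " bands, scene has ", nb)
  }
  out <- scn$data
  for (b in seq_len(nb)) {
    dn <- scn$data[, , b]
    na <- if (is.na(scn$nodata)) is.na(dn) else dn == scn$nodata
    L <- if (calibration$convention == "divide") {
      dn / calibration$gain[b] + calibration$bias[b]
    } else {
      dn * calibration$gain[b] + calibration$bias[b]
    }
    L[na] <- scn$nodata
    out[, , b] <- L
  }
  scn$data <- out
  scn$state <- "TOA_radiance"
  scn
}

#' Convert TOA radiance back to digital numbers
#'
#' Exact inverse of [dn_to_radiance()] up to integer rounding and clipping
#' at the sensor bit depth. Used by the scene simulator and for round-trip
#' checks.
#'
#' @param scn A `wq_scene` in `TOA_radiance` state.
#' @param calibration A [radiometric_calibration()].
#' @param bit_depth Integer DN bit depth (default 12); DNs are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param round_dn Round DNs to integers (default TRUE).
#' @return The scene in `DN` state.
#' @export
radiance_to_dn <- function(scn, calibration, bit_depth = 12, round_dn = TRUE) {
  assert_state(scn, "TOA_radiance")
  nb <- n_bands(scn$band_set)
  dn_max <- 2^bit_depth - 1
  out <- scn$data
  for (b in seq_len(nb)) {
    L <- scn$data[, , b]
    na <- if (is.na(scn$nodata)) is.na(L) else L == scn$nodata
    dn <- if (calibration$convention == "divide") {
      (L - calibration$bias[b]) * calibration$gain[b]
    } else {
      (L - calibration$bias[b]) / calibration$gain[b]
    }
    if (round_dn) dn <- round(dn)
    dn <- pmin(pmax(dn, 0), dn_max)
    dn[na] <- scn$nodata
    out[, , b] <- dn
  }
  scn$data <- out
  scn$state <- "DN"
  scn
}

#' Forward Lambertian TOA radiance model
#'
#' Computes TOA radiance from surface reflectance under the Lambertian
#' coupling L = L0 + (I0 Tg Tud / pi) * rho / (1 - S rho).
#'
#' @param rho Surface reflectance; vector/array per band, or a list of one
#'   element per band when `band` is `NULL`.
#' @param terms A [atmospheric_terms()].
#' @param band Band index (or label) selecting the per-band terms when
#'   `rho` is a single band's values.
#' @return Radiance, same shape as `rho`.
#' @export
toa_radiance_forward <- function(rho, terms, band = 1) {
  stopifnot(inherits(terms, "wq_atmosphere"))
  if (is.character(band)) band <- match(band, terms$labels)
  S <- terms$S[band]
  bad <- !is.na(rho) & S > 0 & rho >= 1 / S
  if (any(bad)) {
    stop("reflectance >= 1/S: Lambertian coupling is singular")
  }
  terms$L0[band] + atm_k(terms)[band] * rho / (1 - S * rho)
}

#' Invert TOA radiance to surface reflectance
#'
#' Solves the Lambertian coupling for rho: with
#' y = pi (L - L0) / (I0 Tg Tud), rho = y / (1 + S y). This is the exact
#' algebraic inverse of [toa_radiance_forward()]. Negative retrieved
#' reflectance (over-corrected dark water) is retained but flagged, and
#' values are clipped to `[-0.05, 1]` with clipping counts recorded in the
#' scene `flags`.
#'
#' @param scn A `wq_scene` in `TOA_radiance` state.
#' @param terms A [atmospheric_terms()].
#' @return The scene in `surface_reflectance` state. `scn$flags` gains
#'   `n_negative` and `n_clipped` per band.
#' @export
invert_surface_reflectance <- function(scn, terms) {
  assert_state(scn, "TOA_radiance")
  stopifnot(inherits(terms, "wq_atmosphere"))
  nb <- n_bands(scn$band_set)
  if (length(terms$L0) != nb) stop("atmospheric terms band count mismatch")
  k <- atm_k(terms)
  out <- scn$data
  n_negative <- integer(nb)
  n_clipped <- integer(nb)
  for (b in seq_len(nb)) {
    L <- scn$data[, , b]
    na <- if (is.na(scn$nodata)) is.na(L) else L == scn$nodata
    y <- (L - terms$L0[b]) / k[b]
    rho <- y / (1 + terms$S[b] * y)
    n_negative[b] <- sum(rho < 0 & !na, na.rm = TRUE)
    clip <- (!na & !is.na(rho)) & (rho < -0.05 | rho > 1)
    n_clipped[b] <- sum(clip)
    rho <- pmin(pmax(rho, -0.05), 1)
    rho[na] <- scn$nodata
    out[, , b] <- rho
  }
  scn$data <- out
  scn$state <- "surface_reflectance"
  scn$flags$n_negative <- n_negative
  scn$flags$n_clipped <- n_clipped
  scn
}

# scalar/vector inversion used outside a scene context
invert_reflectance_values <- function(L, terms, band = 1) {
  if (is.character(band)) band <- match(band, terms$labels)
  y <- (L - terms$L0[band]) / atm_k(terms)[band]
  y / (1 + terms$S[band] * y)
}

#' Convolve a hyperspectral reflectance spectrum to sensor bands
#'
#' Band-averages a continuous remote-sensing reflectance (Rrs) curve over
#' each band's wavelength range under a rectangular spectral response, by
#' trapezoidal integration on a fine grid with linear interpolation of the
#' input samples.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm), ascending.
#' @param rrs Numeric vector of Rrs values at those wavelengths.
#' @param bands A [band_set()]; the spectrum must cover every band range.
#' @param grid_step_nm Integration grid step in nm (default 0.1).
#' @return Named numeric vector, one band-averaged Rrs per band.
#' @export
convolve_to_bands <- function(wavelength_nm, rrs, bands = band_set(),
                              grid_step_nm = 0.1) {
  stopifnot(length(wavelength_nm) == length(rrs), length(wavelength_nm) >= 2)
  o <- order(wavelength_nm)
  wavelength_nm <- wavelength_nm[o]
  rrs <- rrs[o]
  out <- numeric(n_bands(bands))
  names(out) <- bands$label
  for (b in seq_len(n_bands(bands))) {
    lo <- bands$wl_min_nm[b]
    hi <- bands$wl_max_nm[b]
    if (min(wavelength_nm) > lo || max(wavelength_nm) < hi) {
      stop("spectrum does not cover band ", bands$label[b],
           " (", lo, "-", hi, " nm)")
    }
    grid <- seq(lo, hi, by = grid_step_nm)
    if (grid[length(grid)] < hi) grid <- c(grid, hi)
    vals <- stats::approx(wavelength_nm, rrs, xout = grid)$y
    # trapezoid rule over the rectangular response, normalized by width
    w <- diff(grid)
    out[b] <- sum(w * (vals[-1] + vals[-length(vals)]) / 2) / (hi - lo)
  }
  out
}

#' Validate atmospheric correction against in-situ spectra
#'
#' Compares image-derived band reflectances with in-situ Rrs convolved to
#' the same bands, pooling all bands and points: returns the RMSE, the
#' least-squares line of image values on in-situ values, and the same
#' statistics per band on request.
#'
#' @param image_spectra Numeric matrix (points x bands) of image-derived
#'   reflectance.
#' @param insitu_spectra Numeric matrix of identical shape, in-situ
#'   (convolved) reflectance.
#' @param per_band Also return per-band RMSE (default FALSE).
#' @return A list with `rmse`, `slope`, `intercept`, `r_squared`, `n`,
#'   and optionally `per_band_rmse`.
#' @export
validate_correction <- function(image_spectra, insitu_spectra,
                                per_band = FALSE) {
  image_spectra <- as.matrix(image_spectra)
  insitu_spectra <- as.matrix(insitu_spectra)
  if (!all(dim(image_spectra) == dim(insitu_spectra))) {
    stop("image and in-situ spectra dimensions differ")
  }
  if (nrow(image_spectra) < 2) stop("need at least 2 paired spectra")
  x <- as.vector(insitu_spectra)
  y <- as.vector(image_spectra)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  rmse <- sqrt(mean((y - x)^2))
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- list(
    rmse = rmse,
    intercept = unname(fit$coefficients[1]),
    slope = unname(fit$coefficients[2]),
    r_squared = stats::cor(x, y)^2,
    n = length(x)
  )
  if (per_band) {
    out$per_band_rmse <- sqrt(colMeans((image_spectra - insitu_spectra)^2,
                                       na.rm = TRUE))
  }
  out
}
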