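#' Configuration for the synthetic field-campaign and scene generator
#'
#' The generator emulates a hypertrophic coastal lagoon: very high
#' phytoplankton biomass (Chl-a), very low transparency (SDD), and high
#' suspended-matter loads whose organic fraction tracks the phytoplankton.
#' Default variable ranges are the observed ranges of the study system:
#' Chl-a 21-331 ug/L, SDD 0.16-0.42 m, TSM 39-136 mg/L, PIM 2-75 mg/L,
#' POM 7-60 mg/L.
#'
#' @param n_samples Number of field samples to generate (>= 1).
#' @param seed Integer seed; every draw is reproducible under it.
#' @param variable_ranges Named list of `c(min, max)` per variable
#'   (`chl_a`, `sdd`, `tsm`, `pim`, `pom`); defaults above.
#' @param noise_cv Relative multiplicative noise on synthesized
#'   reflectance, in `[0, 1)`. Default 0.05.
#' @param scene_shape Integer `c(rows, cols)` for simulated scenes.
#' @param water_fraction Proportion of scene pixels that are water, in
#'   (0, 1].
#' @param bit_depth DN bit depth for simulated scenes (default 12).
#' @param b1_baseline Blue-band reflectance baseline used by the
#'   bio-optical forward model (default 0.06).
#' @param correlation_length Spatial correlation length (pixels) of the
#'   simulated fields.
#' @param missing_rate Fraction of samples whose gravimetric block
#'   (TSM/PIM/POM) is missing, emulating campaigns without gravimetry.
#'
#' @return A `wq_sim_config` list.
#' @export
sim_config <- function(n_samples = 22, seed = 1,
                       variable_ranges = NULL,
                       noise_cv = 0.05,
                       scene_shape = c(100L, 100L),
                       water_fraction = 0.8,
                       bit_depth = 12,
                       b1_baseline = 0.06,
                       correlation_length = 8,
                       missing_rate = 0) {
  defaults <- list(chl_a = c(21, 331), sdd = c(0.16, 0.42),
                   tsm = c(39, 136), pim = c(2, 75), pom = c(7, 60))
  if (is.null(variable_ranges)) variable_ranges <- list()
  variable_ranges <- utils::modifyList(defaults, variable_ranges)
  for (v in names(variable_ranges)) {
    r <- variable_ranges[[v]]
    if (length(r) != 2 || !(r[1] < r[2])) {
      stop("variable_ranges$", v, " must be c(min, max) with min < max")
    }
  }
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (noise_cv < 0 || noise_cv >= 1) stop("noise_cv must lie in [0, 1)")
  if (water_fraction <= 0 || water_fraction > 1) {
    stop("water_fraction must lie in (0, 1]")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0, 1]")
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         variable_ranges = variable_ranges, noise_cv = noise_cv,
         scene_shape = as.integer(scene_shape),
         water_fraction = water_fraction, bit_depth = bit_depth,
         b1_baseline = b1_baseline,
         correlation_length = correlation_length,
         missing_rate = missing_rate),
    class = "wq_sim_config"
  )
}

# Latent-factor loadings: each scaled variable is a convex combination
# q = w*z + (1-w)*u of the shared trophic state z ~ U(0,1) and an
# independent U(0,1), so q stays in [0,1] exactly and the population
# correlation between two variables with loadings w1, w2 is
# w1*w2 / sqrt((w1^2+(1-w1)^2)(w2^2+(1-w2)^2)). The defaults put the
# Chl-a/SDD correlation at -0.845 and TSM/POM near 0.87, matching the
# observed structure of the study system.
.trophic_loadings <- c(chl_a = 0.7, sdd = 0.7, tsm = 0.8, pom = 0.65)

scale_to_range <- function(q, range) range[1] + q * (range[2] - range[1])

# Draw the five variables from the latent trophic factor. z and the u's
# are matrices or vectors of identical shape.
latent_to_variables <- function(z, u_chl, u_sdd, u_tsm, u_pom, ranges) {
  w <- .trophic_loadings
  chl <- scale_to_range(w["chl_a"] * z + (1 - w["chl_a"]) * u_chl,
                        ranges$chl_a)
  sdd <- scale_to_range(w["sdd"] * (1 - z) + (1 - w["sdd"]) * u_sdd,
                        ranges$sdd)
  tsm <- scale_to_range(w["tsm"] * z + (1 - w["tsm"]) * u_tsm, ranges$tsm)
  pom <- scale_to_range(w["pom"] * z + (1 - w["pom"]) * u_pom, ranges$pom)
  # inorganic fraction is the residual of the additivity identity
  pim <- tsm - pom
  neg <- !is.na(pim) & pim < 0
  if (any(neg)) { # only reachable under user-supplied inconsistent ranges
    pom[neg] <- tsm[neg]
    pim[neg] <- 0
  }
  list(chl_a = chl, sdd = sdd, tsm = tsm, pim = pim, pom = pom)
}

#' Simulate a field campaign
#'
#' Generates water-quality samples with the statistical structure the
#' downstream analysis assumes: a shared latent trophic factor makes
#' Chl-a and SDD strongly negatively associated and TSM and POM strongly
#' positively associated, the additivity TSM = PIM + POM holds exactly
#' (PIM is the gravimetric residual), and every variable stays inside its
#' configured range.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `wq_field_samples` with columns `point_id`,
#'   `campaign_date`, `chl_a`, `sdd`, `tsm`, `pim`, `pom`.
#' @examples
#' fs <- simulate_field_campaign(sim_config(n_samples = 22, seed = 1))
#' stopifnot(all(abs(fs$tsm - fs$pim - fs$pom) < 1e-9))
#' @export
simulate_field_campaign <- function(config = sim_config()) {
  stopifnot(inherits(config, "wq_sim_config"))
  n <- config$n_samples
  if (n < 2) {
    stop("n_samples must be >= 2 to realize the correlation structure")
  }
  with_seed(config$seed, {
    z <- stats::runif(n)
    u <- replicate(4, stats::runif(n))
    vars <- latent_to_variables(z, u[, 1], u[, 2], u[, 3], u[, 4],
                                config$variable_ranges)
    # campaigns on distinct dates, 4-5 points each like a multi-year survey
    n_campaigns <- max(1L, ceiling(n / 5L))
    base_dates <- as.Date("2018-02-16") + sort(
      sample.int(2000L, n_campaigns, replace = FALSE))
    campaign <- rep(seq_len(n_campaigns), length.out = n)
    out <- tibble::tibble(
      point_id = sprintf("P%03d", seq_len(n)),
      campaign_date = base_dates[campaign],
      chl_a = vars$chl_a, sdd = vars$sdd,
      tsm = vars$tsm, pim = vars$pim, pom = vars$pom
    )
    if (config$missing_rate > 0) {
      drop <- stats::runif(n) < config$missing_rate
      out$tsm[drop] <- NA_real_
      out$pim[drop] <- NA_real_
      out$pom[drop] <- NA_real_
    }
    class(out) <- c("wq_field_samples", class(out))
    out
  })
}

#' Synthesize a four-band reflectance spectrum from a water sample
#'
#' Inverts the published linear retrieval models to construct reflectance
#' consistent with a sample's Chl-a and POM: the Chl-a model fixes the
#' normalized difference of B4 and B1 around a configurable B1 baseline
#' (so B4 = B1 (1+d)/(1-d) with d the index value), the POM model fixes
#' the B3/B4 simple ratio, and B2 is the mean of B1 and B3 (the green
#' band carries no constraint). Optional multiplicative Gaussian noise at
#' coefficient of variation `noise_cv` is applied per band. At
#' `noise_cv = 0`, applying the published Chl-a and POM models to the
#' output recovers the generating values exactly.
#'
#' @param sample A single complete sample: list/row with `chl_a`, `sdd`,
#'   `tsm`, `pim`, `pom`.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Seed for the noise draw (ignored at `noise_cv = 0`).
#' @param b1_baseline Blue-band reflectance baseline.
#' @return Named reflectance vector `c(B1, B2, B3, B4)`, all in (0, 1).
#' @examples
#' s <- list(chl_a = 198.95, sdd = 0.26, tsm = 100, pim = 60, pom = 40)
#' r <- bio_optical_forward(s, noise_cv = 0)
#' all.equal(unname((r["B4"] - r["B1"]) / (r["B4"] + r["B1"])), 0)
#' @export
bio_optical_forward <- function(sample, noise_cv = 0, seed = NULL,
                                b1_baseline = 0.06) {
  need <- .wq_variables
  vals <- vapply(need, function(v) {
    x <- sample[[v]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  if (anyNA(vals)) {
    stop("sample is incomplete; missing: ",
         paste(need[is.na(vals)], collapse = ", "))
  }
  p <- .pub_perusat
  d <- (vals["chl_a"] - p$chl_a$intercept) / p$chl_a$slope  # ND(B4, B1)
  s <- (vals["pom"] - p$pom$intercept) / p$pom$slope        # B3 / B4
  if (abs(d) >= 1) {
    stop("band B4: Chl-a of ", vals["chl_a"],
         " implies |ND(B4,B1)| >= 1, reflectance outside (0, 1)")
  }
  b1 <- b1_baseline
  b4 <- b1 * (1 + d) / (1 - d)
  b3 <- s * b4
  b2 <- (b1 + b3) / 2
  rho <- c(B1 = unname(b1), B2 = unname(b2), B3 = unname(b3),
           B4 = unname(b4))
  if (noise_cv > 0) {
    rho <- with_seed(seed, rho * (1 + noise_cv * stats::rnorm(4)))
  }
  bad <- !(rho > 0 & rho < 1)
  if (any(bad)) {
    stop("band ", paste(names(rho)[bad], collapse = ", "),
         ": synthesized reflectance outside (0, 1)")
  }
  rho
}

#' Default atmospheric terms for simulated scenes
#'
#' Plausible clear-sky mid-latitude terms for a blue/green/red/NIR band
#' set: path radiance and spherical albedo decrease with wavelength,
#' transmittances increase.
#' @return A [atmospheric_terms()] object.
#' @export
default_sim_atmosphere <- function() {
  atmospheric_terms(
    L0 = c(25, 18, 12, 6),
    I0 = c(1900, 1820, 1510, 1040),
    Tg = c(0.95, 0.93, 0.94, 0.96),
    Tud = c(0.80, 0.82, 0.84, 0.86),
    S = c(0.14, 0.12, 0.10, 0.08),
    labels = c("B1", "B2", "B3", "B4")
  )
}

#' Default radiometric calibration for simulated scenes
#'
#' Gains chosen so that the radiance range of the simulated lagoon
#' (including bright land in every band) spans most of the 12-bit DN
#' range, which keeps quantization error small relative to the retrieval
#' models' sensitivity.
#' @return A [radiometric_calibration()] object (`divide` convention).
#' @export
default_sim_calibration <- function() {
  radiometric_calibration(gain = c(55, 55, 39, 50), bias = c(0, 0, 0, 0),
                          convention = "divide",
                          labels = c("B1", "B2", "B3", "B4"))
}

# land surface reflectance used by the simulator (vegetated land: bright NIR)
.land_reflectance <- c(B1 = 0.10, B2 = 0.12, B3 = 0.15, B4 = 0.26)

#' Simulate a DN-level scene with ground truth
#'
#' Builds smooth spatial fields of the five water-quality variables over
#' the water pixels (driven by a spatially correlated latent trophic
#' field), synthesizes per-pixel reflectance with the bio-optical forward
#' model, places land (bright-NIR) pixels in a block occupying
#' `1 - water_fraction` of the scene, pushes reflectance through the
#' forward Lambertian TOA model and inverse radiometric calibration, and
#' rounds to integer DNs at the configured bit depth. Truth rasters are
#' returned for recovery tests.
#'
#' @param config A [sim_config()].
#' @param atmosphere A [atmospheric_terms()]; default
#'   [default_sim_atmosphere()].
#' @param calibration A [radiometric_calibration()]; default
#'   [default_sim_calibration()].
#' @param date Scene acquisition date.
#' @return A list of class `wq_sim_scene`: `scene` (a `wq_scene` in DN
#'   state), `truth` (list of matrices `chl_a`, `sdd`, `tsm`, `pim`,
#'   `pom`, NA over land), `water_mask` (logical matrix),
#'   `reflectance` (noise-free surface-reflectance array, the
#'   pre-quantization truth), `atmosphere`, `calibration`, `config`.
#' @export
simulate_scene <- function(config = sim_config(),
                           atmosphere = default_sim_atmosphere(),
                           calibration = default_sim_calibration(),
                           date = as.Date("2021-07-16")) {
  stopifnot(inherits(config, "wq_sim_config"))
  if (config$water_fraction <= 0 || config$water_fraction > 1) {
    stop("water_fraction must lie in (0, 1]")
  }
  nr <- config$scene_shape[1]
  nc <- config$scene_shape[2]
  with_seed(config$seed, {
    z <- smooth_uniform_field(nr, nc, config$correlation_length)
    us <- replicate(4, smooth_uniform_field(nr, nc,
                                            config$correlation_length),
                    simplify = FALSE)
    vars <- latent_to_variables(z, us[[1]], us[[2]], us[[3]], us[[4]],
                                config$variable_ranges)
    # land occupies the rightmost columns
    n_land_cols <- round((1 - config$water_fraction) * nc)
    water <- matrix(TRUE, nr, nc)
    if (n_land_cols > 0) water[, seq(nc - n_land_cols + 1, nc)] <- FALSE

    p <- .pub_perusat
    d <- (vars$chl_a - p$chl_a$intercept) / p$chl_a$slope
    s <- (vars$pom - p$pom$intercept) / p$pom$slope
    b1 <- matrix(config$b1_baseline, nr, nc)
    b4 <- b1 * (1 + d) / (1 - d)
    b3 <- s * b4
    b2 <- (b1 + b3) / 2
    rho <- array(NA_real_, c(nr, nc, 4))
    rho[, , 1] <- b1; rho[, , 2] <- b2; rho[, , 3] <- b3; rho[, , 4] <- b4
    if (config$noise_cv > 0) {
      rho <- rho * (1 + config$noise_cv * array(stats::rnorm(nr * nc * 4),
                                                c(nr, nc, 4)))
    }
    for (b in 1:4) {
      plane <- rho[, , b]
      plane[!water] <- .land_reflectance[b]
      if (any(plane <= 0 | plane >= 1)) {
        stop("band B", b, ": simulated reflectance outside (0, 1); ",
             "reduce noise_cv or adjust ranges")
      }
      rho[, , b] <- plane
    }
    for (v in .wq_variables) vars[[v]][!water] <- NA_real_

    rad <- rho
    for (b in 1:4) {
      rad[, , b] <- toa_radiance_forward(rho[, , b], atmosphere, band = b)
    }
    scn <- scene(rad, state = "TOA_radiance", band_set = band_set(),
                 date = date)
    scn <- radiance_to_dn(scn, calibration, bit_depth = config$bit_depth)
    structure(
      list(scene = scn, truth = vars[.wq_variables], water_mask = water,
           reflectance = rho, atmosphere = atmosphere,
           calibration = calibration, config = config),
      class = "wq_sim_scene"
    )
  })
}
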