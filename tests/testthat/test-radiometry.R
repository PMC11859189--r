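test_that("band set defaults match the sensor definition and reject bad input", {
  bs <- band_set()
  expect_equal(bs$label, c("B1", "B2", "B3", "B4"))
  expect_equal(bs$wl_min_nm, c(450, 530, 630, 752))
  expect_equal(bs$wl_max_nm, c(520, 590, 700, 885))
  expect_equal(unique(bs$resolution_m), 2.8)
  expect_error(band_set(labels = c("B1", "B1"), wl_min = c(450, 530),
                        wl_max = c(520, 590)), "duplicate")
  expect_error(band_set(labels = c("B1", "B2"), wl_min = c(450, 500),
                        wl_max = c(520, 590)), "non-overlapping")
})

test_that("DN to radiance is affine, monotone, and supports both conventions", {
  bs <- band_set()
  dn <- array(0, c(2, 2, 4))
  for (b in 1:4) dn[, , b] <- matrix(c(0, 100, 200, 4095), 2, 2)
  scn <- scene(dn, state = "DN", band_set = bs)
  cal_div <- radiometric_calibration(gain = rep(2, 4), bias = rep(1.5, 4))
  cal_mul <- radiometric_calibration(gain = rep(2, 4), bias = rep(1.5, 4),
                                     convention = "multiply")
  r_div <- dn_to_radiance(scn, cal_div)
  r_mul <- dn_to_radiance(scn, cal_mul)
  # DN = 0 gives the bias under either convention
  expect_equal(r_div$data[1, 1, 1], 1.5)
  expect_equal(r_mul$data[1, 1, 1], 1.5)
  # DN = 100, gain 2, bias 0, divide -> 50
  cal0 <- radiometric_calibration(gain = rep(2, 4))
  expect_equal(dn_to_radiance(scn, cal0)$data[2, 1, 1], 50)
  # affine and monotone in DN
  expect_true(all(diff(c(r_div$data[1, 1, 1], r_div$data[2, 1, 1],
                         r_div$data[1, 2, 1], r_div$data[2, 2, 1])) > 0))
  expect_true(all(r_mul$data >= r_div$data - 1e-12))
  # state machine: no double conversion
  expect_error(dn_to_radiance(r_div, cal_div), "state")
  expect_error(radiometric_calibration(gain = c(0, 1, 1, 1)), "> 0")
})

test_that("radiance_to_dn then dn_to_radiance is identity within rounding", {
  cal <- radiometric_calibration(gain = c(55, 55, 39, 50))
  rad <- array(runif(4 * 5 * 5, 10, 70), c(5, 5, 4))
  scn <- scene(rad, state = "TOA_radiance")
  back <- dn_to_radiance(radiance_to_dn(scn, cal, bit_depth = 12), cal)
  # rounding error bounded by half a DN step per band
  for (b in 1:4) {
    expect_lt(max(abs(back$data[, , b] - rad[, , b])), 0.5 / cal$gain[b] + 1e-12)
  }
})

test_that("Lambertian forward model matches its closed form and limits", {
  tr <- example_terms()
  # rho = 0 returns the path radiance
  expect_equal(toa_radiance_forward(0, tr), 20)
  # unit-transfer limit: S = 0, L0 = 0, I0*Tg*Tud = pi
  tr1 <- atmospheric_terms(L0 = 0, I0 = pi, Tg = 1, Tud = 1, S = 0)
  expect_equal(toa_radiance_forward(0.37, tr1), 0.37)
  # frozen independent numeric oracle
  expect_equal(toa_radiance_forward(0.05, tr), 38.280769282092,
               tolerance = 1e-12)
  # singularity guard
  tr2 <- atmospheric_terms(L0 = 0, I0 = 100, Tg = 1, Tud = 1, S = 0.5)
  expect_error(toa_radiance_forward(2.5, tr2), "singular")
})

test_that("reflectance inversion is the exact algebraic inverse", {
  tr <- example_terms()
  # L = L0 -> rho = 0
  expect_equal(invert_reflectance_values(20, tr), 0)
  # forward then invert over a grid recovers rho to 1e-12
  for (rho in c(0.001, 0.01, 0.05, 0.2, 0.6, 0.95)) {
    L <- toa_radiance_forward(rho, tr)
    expect_equal(invert_reflectance_values(L, tr), rho, tolerance = 1e-12)
  }
  # S = 0 closed form
  tr0 <- atmospheric_terms(L0 = 5, I0 = 1200, Tg = 0.9, Tud = 0.85, S = 0)
  L <- 40
  expect_equal(invert_reflectance_values(L, tr0),
               pi * (L - 5) / (1200 * 0.9 * 0.85))
})

test_that("scene-level inversion flags negatives and clips to [-0.05, 1]", {
  tr <- atmospheric_terms(L0 = rep(10, 4), I0 = rep(1000, 4),
                          Tg = rep(1, 4), Tud = rep(1, 4), S = rep(0, 4))
  rad <- array(10, c(2, 2, 4))
  rad[1, 1, ] <- 5     # below path radiance: negative but within [-0.05, 0)
  rad[1, 2, ] <- -30   # strongly over-corrected: clipped to -0.05
  rad[2, 2, ] <- 1e5   # absurdly bright: clipped to 1
  scn <- invert_surface_reflectance(scene(rad, state = "TOA_radiance"), tr)
  expect_equal(scn$state, "surface_reflectance")
  expect_lt(scn$data[1, 1, 1], 0)
  expect_gt(scn$data[1, 1, 1], -0.05)
  expect_equal(scn$data[1, 2, 1], -0.05)  # clipped from below
  expect_equal(scn$data[2, 2, 1], 1)
  expect_equal(scn$flags$n_negative, rep(2L, 4))
  expect_equal(scn$flags$n_clipped, rep(2L, 4))
  expect_true(all(scn$data <= 1))
})

test_that("band convolution is exact for flat/linear spectra and matches quadrature", {
  wl <- seq(400, 950, by = 0.1)
  # flat spectrum: every band equals the constant
  expect_equal(unname(convolve_to_bands(wl, rep(0.02, length(wl)))),
               rep(0.02, 4), tolerance = 1e-12)
  # linear spectrum: band mean equals the midpoint value
  rrs <- 0.01 + 2e-5 * wl
  mid <- c((450 + 520) / 2, (530 + 590) / 2, (630 + 700) / 2,
           (752 + 885) / 2)
  expect_equal(unname(convolve_to_bands(wl, rrs)), 0.01 + 2e-5 * mid,
               tolerance = 1e-10)
  # smooth spectrum vs frozen fine-grid quadrature oracle
  f <- function(w) 0.02 + 0.01 * sin(w / 40) + 5e-6 * (w - 600)
  got <- convolve_to_bands(wl, f(wl))
  expect_equal(unname(got),
               c(0.0156778164, 0.0288031516, 0.0133618197, 0.0270769440),
               tolerance = 1e-6)
  # coverage gap names the band
  expect_error(convolve_to_bands(seq(500, 900, 1), rep(0.02, 401)), "B1")
})

test_that("correction validation returns pooled RMSE and the fit line", {
  x <- matrix(runif(40, 0, 0.1), 10, 4)
  expect_equal(validate_correction(x, x)$rmse, 0)
  off <- validate_correction(x + 0.1, x)
  expect_equal(off$rmse, 0.1, tolerance = 1e-12)
  set.seed(3)
  y <- x + matrix(rnorm(40, 0, 0.01), 10, 4)
  v <- validate_correction(y, x, per_band = TRUE)
  expect_equal(v$rmse, sqrt(mean((y - x)^2)), tolerance = 1e-12)
  expect_length(v$per_band_rmse, 4)
  expect_error(validate_correction(x, x[1:5, ]), "differ")
})
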