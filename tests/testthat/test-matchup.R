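test_that("ROI window sizing follows the 100-150 pixel protocol", {
  scn <- make_uniform_scene(40, 40, c(B1 = 0.03, B2 = 0.04, B3 = 0.05,
                                      B4 = 0.02))
  roi <- extract_roi(scn, x = 20, y = -20)
  # on uniform water the window is 12 x 12 = 144 pixels
  expect_equal(roi$side, 12)
  expect_equal(roi$n_pixels, 144)
  expect_equal(unname(roi$spectrum["B1"]), 0.03)
  expect_equal(unname(roi$spectrum_sd["B1"]), 0)
  expect_error(extract_roi(scn, x = 200, y = -20), "outside")
})

test_that("ROI means over a straddling window match direct enumeration", {
  nr <- 40; nc <- 40
  arr <- array(0, c(nr, nc, 4))
  set.seed(5)
  for (b in 1:4) arr[, , b] <- matrix(runif(nr * nc, 0.01, 0.2), nr, nc)
  scn <- scene(arr, state = "surface_reflectance")
  mask <- matrix(TRUE, nr, nc)
  mask[, 25:40] <- FALSE  # land block to the east
  # center at row 20, col 22 near the land edge; window straddles the mask
  roi <- extract_roi(scn, x = 21.5, y = -19.5, mask = mask, max_side = 31)
  lo <- floor((roi$side - 1) / 2); hi <- floor(roi$side / 2)
  rows <- (20 - lo):(20 + hi); cols <- (22 - lo):(22 + hi)
  sel <- mask[rows, cols]
  expect_equal(roi$n_pixels, sum(sel))
  expect_gte(roi$n_pixels, 100)
  expect_lte(roi$n_pixels, 150)
  for (b in 1:4) {
    expect_equal(unname(roi$spectrum[b]), mean(arr[rows, cols, b][sel]))
  }
  # ROI means are translation invariant when contents are identical
  scn2 <- scene(arr[c(2:nr, 1), , , drop = FALSE],
                state = "surface_reflectance")
  roi2 <- extract_roi(scn2, x = 21.5, y = -18.5,
                      mask = mask[c(2:nr, 1), ])
  expect_equal(roi2$spectrum, roi$spectrum)
  # impossible target: tiny water patch
  tiny <- matrix(FALSE, nr, nc); tiny[18:22, 18:22] <- TRUE
  expect_error(extract_roi(scn, x = 20, y = -20, mask = tiny), "water pixels")
})

test_that("matchup pairing respects the time window and reports the unpaired", {
  mk <- function(d) make_uniform_scene(20, 20, date = as.Date(d))
  scenes <- list(mk("2018-02-19"), mk("2019-10-05"), mk("2023-04-20"))
  samples <- tibble::tibble(
    point_id = c("a", "b", "c", "d"),
    campaign_date = as.Date(c("2018-02-16", "2019-10-08", "2023-04-20",
                              "2019-10-13")),
    chl_a = c(100, 150, 200, 250))
  res <- build_matchups(scenes, samples, max_lag_days = 3)
  # 3-day lag accepted, same-day lag 0, 5-day lag excluded
  expect_equal(res$matchups$lag_days, c(3L, 3L, 0L))
  expect_equal(res$matchups$image_date[1], as.Date("2018-02-19"))
  expect_equal(nrow(res$unpaired), 1)
  expect_equal(res$unpaired$point_id, "d")
  expect_lte(nrow(res$matchups), nrow(samples))
  expect_error(build_matchups(list(), samples), "empty")
  # equidistant scenes tie toward the earlier one
  scns <- list(mk("2020-05-10"), mk("2020-05-14"))
  s1 <- tibble::tibble(point_id = "e",
                       campaign_date = as.Date("2020-05-12"), chl_a = 1)
  expect_equal(build_matchups(scns, s1)$matchups$image_date,
               as.Date("2020-05-10"))
})

test_that("matchups carry ROI spectra when point coordinates are given", {
  scn <- make_uniform_scene(40, 40, c(B1 = 0.031, B2 = 0.042, B3 = 0.053,
                                      B4 = 0.024), date = as.Date("2021-07-16"))
  samples <- tibble::tibble(point_id = "p1",
                            campaign_date = as.Date("2021-07-15"),
                            chl_a = 120, sdd = 0.3, tsm = 80, pim = 50,
                            pom = 30)
  points <- data.frame(point_id = "p1", x = 20, y = -20)
  res <- build_matchups(list(scn), samples, points = points)
  expect_equal(res$matchups$B1, 0.031)
  expect_equal(res$matchups$n_pixels, 144)
  expect_equal(res$matchups$chl_a, 120)
  expect_equal(res$matchups$lag_days, 1L)
})

test_that("spectral stability t-test matches the reference implementation", {
  # identical sets: stable with t = 0
  a <- c(0.02, 0.03, 0.04, 0.05)
  st <- spectral_stability_test(a, a)
  expect_equal(st$statistic, 0)
  expect_true(st$stable)
  # large constant shift versus tiny spread: unstable
  set.seed(8)
  x <- rnorm(20, 0.05, 0.001)
  st2 <- spectral_stability_test(x, x + 0.05)
  expect_false(st2$stable)
  # constant nonzero difference: p = 0 convention
  st3 <- spectral_stability_test(a, a + 0.01)
  expect_equal(st3$p_value, 0)
  expect_false(st3$stable)
  # Gaussian pairs with known shift: p equals stats::t.test to 1e-10
  set.seed(21)
  y <- x + rnorm(20, 0.002, 0.003)
  st4 <- spectral_stability_test(x, y)
  expect_equal(st4$p_value, t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-10)
  # pooled mode falls back to the two-sample test
  st5 <- spectral_stability_test(x, y, mode = "pooled")
  expect_equal(st5$p_value, t.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("cross-correlation gates Pearson/Spearman on normality", {
  set.seed(12)
  n <- 60
  x <- rnorm(n, 50, 5)
  df <- data.frame(chl_a = x, sdd = -x + 100,      # exact linear inverse
                   tsm = exp(x / 10))              # monotone, non-normal
  cm <- cross_correlate(df)
  expect_equal(cm$r["chl_a", "sdd"], -1)
  # monotone nonlinear pair failing normality uses Spearman: rho = 1
  expect_equal(cm$method["chl_a", "tsm"], "spearman")
  expect_equal(cm$r["chl_a", "tsm"], 1)
  # symmetry and unit diagonal hold exactly
  expect_identical(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  # constant variable reported as missing
  df$pim <- 5
  cm2 <- cross_correlate(df)
  expect_true(is.na(cm2$r["chl_a", "pim"]))
  expect_equal(cm2$method["chl_a", "pim"], "none")
})

test_that("synthetic campaign reproduces the strong TSM-POM association", {
  fs <- simulate_field_campaign(sim_config(n_samples = 1000, seed = 3))
  cm <- cross_correlate(fs)
  expect_gte(cm$r["tsm", "pom"], 0.7)
  expect_equal(cm$n["tsm", "pom"], 1000)
  expect_lt(cm$r["chl_a", "sdd"], -0.6)
})
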