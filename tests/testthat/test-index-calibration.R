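test_that("index enumeration yields all ordered SR and canonical ND pairs", {
  specs <- enumerate_indices(band_set())
  expect_length(specs, 18)  # 4*3 SR + C(4,2) ND
  fams <- vapply(specs, function(s) s$family, character(1))
  expect_equal(sum(fams == "SR"), 12)
  expect_equal(sum(fams == "ND"), 6)
  nds <- specs[fams == "ND"]
  # canonical orientation: longer-wavelength band first
  for (s in nds) expect_gt(match(s$a, band_set()$label),
                           match(s$b, band_set()$label))
  # two bands -> 2 SR + 1 ND
  bs2 <- band_set(labels = c("B1", "B2"), wl_min = c(450, 530),
                  wl_max = c(520, 590))
  expect_length(enumerate_indices(bs2), 3)
  expect_error(index_spec("SR", "B1", "B1"), "differ")
})

test_that("index computation follows the SR and ND formulas", {
  sp <- c(B1 = 0.04, B2 = 0.05, B3 = 0.06, B4 = 0.06)
  expect_equal(compute_index(sp, index_spec("ND", "B4", "B3")), 0)
  expect_equal(compute_index(sp, index_spec("SR", "B4", "B3")), 1)
  expect_equal(compute_index(c(B1 = 0.04, B4 = 0.06),
                             index_spec("ND", "B4", "B1")), 0.2)
  # zero denominator -> NA with warning
  expect_warning(
    v <- compute_index(c(B1 = 0, B4 = 0.06), index_spec("SR", "B4", "B1")),
    "zero")
  expect_true(is.na(v))
  expect_error(compute_index(c(B1 = 0.04), index_spec("SR", "B4", "B1")),
               "lack")
})

test_that("fit families recover known coefficients", {
  x <- seq(0.1, 2, length.out = 50)
  # exact linear: coefficients (slope, intercept), R^2 = 1, RMSE = 0
  f <- fit_model(x, 2 * x + 1, "linear")
  expect_equal(unname(f$coefficients), c(2, 1), tolerance = 1e-12)
  expect_equal(f$stats$r_squared, 1)
  expect_lt(f$stats$rmse, 1e-12)
  # the published Chl-a line from noiseless synthetic pairs
  nd <- seq(-0.5, 0.4, length.out = 30)
  fp <- fit_model(nd, 323.77 * nd + 198.95, "linear")
  expect_equal(unname(fp$coefficients["slope"]), 323.77, tolerance = 1e-9)
  expect_equal(unname(fp$coefficients["intercept"]), 198.95,
               tolerance = 1e-9)
  # exponential recovery from 1% noise
  set.seed(14)
  xe <- runif(200, 0, 1)
  ye <- 3 * exp(2 * xe) * (1 + 0.01 * rnorm(200))
  fe <- fit_model(xe, ye, "exponential")
  expect_equal(unname(fe$coefficients["a"]), 3, tolerance = 0.05)
  expect_equal(unname(fe$coefficients["b"]), 2, tolerance = 0.05)
  # power and logarithmic round-trip on exact data
  fpow <- fit_model(x, 1.7 * x^0.8, "power")
  expect_equal(unname(fpow$coefficients), c(1.7, 0.8), tolerance = 1e-9)
  flog <- fit_model(x, 4 - 2 * log(x), "logarithmic")
  expect_equal(unname(flog$coefficients), c(4, -2), tolerance = 1e-9)
  # polynomial degree 2 exact
  fq <- fit_model(x, 1 + 2 * x - 3 * x^2, "polynomial")
  expect_equal(unname(fq$coefficients), c(-3, 2, 1), tolerance = 1e-9)
  # domain violations name the family
  expect_error(fit_model(c(-1, x), c(1, 2 * x), "power"), "power")
  expect_error(fit_model(x, 2 * x - 1, "exponential"), "exponential")
  expect_error(fit_model(rep(1, 10), rnorm(10), "linear"), "rank-deficient")
})

test_that("cross-validation folds are balanced and stats behave", {
  # n = 21 with k = 10: folds of size 2 or 3 summing to 21
  x <- seq_len(21); y <- 3 * x + 2
  folds <- with(list(), {
    set.seed(1); idx <- sample.int(21)
    lengths(split(idx, rep(1:10, length.out = 21)))
  })
  expect_true(all(folds %in% c(2, 3)))
  expect_equal(sum(folds), 21)
  cv <- crossvalidate(x, y, "linear", k = 10, seed = 1)
  expect_lt(cv$rmse, 1e-9)
  expect_gt(cv$r_squared, 1 - 1e-9)
  expect_equal(cv$k_folds, 10)
  expect_error(crossvalidate(x[1:5], y[1:5], "linear", k = 10), "reduce k")
  expect_error(crossvalidate(x, y, "linear", k = 1), "k must be")
})

test_that("CV RMSE is consistent with the generating noise and exceeds calibration RMSE", {
  set.seed(2)
  rmse_cv <- rmse_cal <- rmse_cv_pooled <- numeric(20)
  for (r in 1:20) {
    x <- runif(500, -0.5, 0.4)
    y <- 323.77 * x + 198.95 + rnorm(500, 0, 5)
    cv <- crossvalidate(x, y, "linear", k = 10, seed = r)
    rmse_cv[r] <- cv$rmse
    rmse_cal[r] <- fit_model(x, y, "linear")$stats$rmse
    rmse_cv_pooled[r] <- cv$rmse_pooled
  }
  expect_gt(mean(rmse_cv), 4.5)
  expect_lt(mean(rmse_cv), 5.5)
  # pooled held-out error exceeds in-sample error in expectation
  expect_gt(mean(rmse_cv_pooled - rmse_cal), 0)
})

test_that("summary statistics match their definitions", {
  s <- summary_stats(c(1, 2, 3), c(2, 3, 4))
  expect_equal(s$bias, 1)
  expect_equal(s$mae, 1)
  expect_equal(s$rmse, 1)
  p <- summary_stats(1:10, 1:10)
  expect_equal(p$rmse, 0); expect_equal(p$bias, 0)
  expect_equal(p$r_squared, 1)
  # printed-table consistency: RMSE 50.8 over range 21-331 -> NRMSE 16%
  s2 <- summary_stats(c(21, 331), c(21, 331) + 50.8,
                      observed_range = c(21, 331))
  expect_equal(round(s2$nrmse_pct), 16)
  # mae <= rmse always
  set.seed(6)
  o <- rnorm(50); pr <- o + rnorm(50)
  s3 <- summary_stats(o, pr)
  expect_lte(s3$mae, s3$rmse)
  # zero observed range: NRMSE missing
  expect_true(is.na(summary_stats(c(2, 2), c(1, 3))$nrmse_pct))
})

test_that("ND orientation is absorbed by the linear fit", {
  mt <- make_linear_matchups(100, seed = 5, noise = 0.05,
                             mechanism = "additive")
  nd <- (mt$B4 - mt$B1) / (mt$B4 + mt$B1)
  a <- crossvalidate(nd, mt$chl_a, "linear", k = 10, seed = 1)
  b <- crossvalidate(-nd, mt$chl_a, "linear", k = 10, seed = 1)
  expect_equal(a$rmse, b$rmse, tolerance = 1e-12)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
})

test_that("the index search recovers the generating index from noisy matchups", {
  hits <- 0
  for (s in 1:10) {
    mt <- make_linear_matchups(200, seed = s, noise = 9,
                               mechanism = "additive")
    rk <- rank_indices(mt, "chl_a", k = 10, seed = s)
    top <- rk$top[1, ]
    if (top$band_comb == "(B4-B1)/(B4+B1)") hits <- hits + 1
    # the linear fit on the generating index recovers the coefficients
    lin <- rk$table[rk$table$band_comb == "(B4-B1)/(B4+B1)" &
                      rk$table$family == "linear", ]
    cf <- lin$fit[[1]]$coefficients
    expect_lt(abs(cf[["slope"]] - 323.77) / 323.77, 0.05)
    expect_lt(abs(cf[["intercept"]] - 198.95) / 198.95, 0.05)
  }
  expect_gte(hits, 9)
})

test_that("rank ordering is deterministic and degenerate targets error", {
  mt <- make_linear_matchups(60, seed = 2, noise = 0.05)
  rk1 <- rank_indices(mt, "chl_a", k = 10, seed = 3)
  rk2 <- rank_indices(mt, "chl_a", k = 10, seed = 3)
  expect_identical(rk1$top[, c("band_comb", "family", "rmse")],
                   rk2$top[, c("band_comb", "family", "rmse")])
  expect_equal(nrow(rk1$top), 5)
  # sorted ascending by cross-validated RMSE
  expect_true(!is.unsorted(rk1$table$rmse))
  mt$chl_a <- 50
  expect_error(rank_indices(mt, "chl_a", k = 10), "failed")
})
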