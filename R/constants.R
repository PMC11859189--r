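# Published retrieval-model coefficients and observed variable ranges.
# These are the printed best per-variable algorithms for the four-band
# sensor (linear fits on two-band indices) and the literature models used
# for the Sentinel-2 comparison. Shared by the registry and the
# bio-optical forward simulator.

.pub_perusat <- list(
  chl_a = list(variable = "chl_a", units = "ug/L",
               index = list(family = "ND", a = "B4", b = "B1"),
               slope = 323.77, intercept = 198.95,
               obs_range = c(21, 331)),
  sdd   = list(variable = "sdd", units = "m",
               index = list(family = "ND", a = "B4", b = "B1"),
               slope = -0.2539, intercept = 0.2608,
               obs_range = c(0.16, 0.42)),
  tsm   = list(variable = "tsm", units = "mg/L",
               index = list(family = "SR", a = "B1", b = "B4"),
               slope = -38.259, intercept = 129.38,
               obs_range = c(39, 136),
               obs_range_printed = c(50, 136)),
  pim   = list(variable = "pim", units = "mg/L",
               index = list(family = "ND", a = "B3", b = "B1"),
               slope = 116.08, intercept = 31.36,
               obs_range = c(2, 75)),
  pom   = list(variable = "pom", units = "mg/L",
               index = list(family = "SR", a = "B3", b = "B4"),
               slope = -18.775, intercept = 70.925,
               obs_range = c(7, 60))
)

# Printed cross-validated statistics of the Table-of-best models, kept for
# consistency checks (NRMSE = 100 * RMSE / observed range).
.pub_perusat_stats <- data.frame(
  variable = c("chl_a", "sdd", "tsm", "pim", "pom"),
  rmse = c(50.8, 0.039, 11.1, 10.7, 4.7),
  nrmse_pct_printed = c(16, 15, 11, 15, 9),
  range_min = c(21, 0.16, 39, 2, 7),
  range_max = c(331, 0.42, 136, 75, 60),
  stringsAsFactors = FALSE
)

# Sentinel-2 literature models (six-band spectrum named by centre
# wavelength: R490, R560, R665, R705, R740, R783).
.pub_sentinel2 <- list(
  chl_a = list(variable = "chl_a", units = "ug/L",
               fun = function(s) {
                 tbdo <- s[["R740"]] * (1 / s[["R665"]] - 1 / s[["R705"]])
                 104.1 * tbdo^2 + 221.1 * tbdo + 2
               },
               formula = "104.1*TBDO^2 + 221.1*TBDO + 2; TBDO = R740*(1/R665 - 1/R705)"),
  sdd   = list(variable = "sdd", units = "m",
               fun = function(s) 0.224 * (s[["R560"]] / s[["R705"]]) + 0.0836,
               formula = "0.224*(R560/R705) + 0.0836"),
  tsm   = list(variable = "tsm", units = "mg/L",
               fun = function(s) 705.98 * s[["R783"]] * s[["R705"]] / s[["R490"]],
               formula = "705.98*R783*R705/R490"),
  pim   = list(variable = "pim", units = "mg/L",
               fun = function(s) 259.4 * s[["R705"]],
               formula = "259.4*R705"),
  pom   = list(variable = "pom", units = "mg/L",
               fun = function(s) 40.48 * s[["R783"]] / s[["R490"]],
               formula = "40.48*R783/R490")
)

.wq_variables <- c("chl_a", "sdd", "tsm", "pim", "pom")
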