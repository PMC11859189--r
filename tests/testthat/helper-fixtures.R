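# Fixtures built in code: synthetic matchup tables and small scenes.

# Matchup table whose chlorophyll column follows the published linear
# ND(B4,B1) model. mechanism "band": multiplicative noise on the
# reflectance bands (the generator's own noise model); "target":
# multiplicative noise on the chlorophyll values with exact spectra;
# "additive": homoscedastic Gaussian noise on chlorophyll.
make_linear_matchups <- function(n = 200, seed = 1, noise = 0.05,
                                 mechanism = c("band", "target",
                                               "additive")) {
  mechanism <- match.arg(mechanism)
  cfg <- sim_config(n_samples = n, seed = seed,
                    noise_cv = if (mechanism == "band") noise else 0)
  fs <- simulate_field_campaign(cfg)
  spectra <- t(vapply(seq_len(n), function(i) {
    bio_optical_forward(fs[i, ],
                        noise_cv = if (mechanism == "band") noise else 0,
                        seed = seed * 100000 + i)
  }, numeric(4)))
  colnames(spectra) <- c("B1", "B2", "B3", "B4")
  out <- cbind(as.data.frame(spectra), fs[, c("chl_a", "sdd", "tsm",
                                              "pim", "pom")])
  if (mechanism != "band") {
    nd <- (out$B4 - out$B1) / (out$B4 + out$B1)
    truth <- 323.77 * nd + 198.95
    set.seed(seed + 777)
    out$chl_a <- if (mechanism == "target") {
      truth * (1 + noise * stats::rnorm(n))
    } else {
      truth + noise * stats::rnorm(n)
    }
  }
  out
}

# Uniform-reflectance scene: every water pixel carries `spectrum`.
make_uniform_scene <- function(nr = 30, nc = 30,
                               spectrum = c(B1 = 0.04, B2 = 0.05,
                                            B3 = 0.06, B4 = 0.03),
                               date = as.Date("2021-07-16")) {
  arr <- array(NA_real_, c(nr, nc, 4))
  for (b in 1:4) arr[, , b] <- spectrum[b]
  scene(arr, state = "surface_reflectance", date = date)
}

example_terms <- function() {
  atmospheric_terms(L0 = 20, I0 = 1500, Tg = 0.95, Tud = 0.8, S = 0.15,
                    labels = "B1")
}
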