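#' Two-band spectral index specification
#'
#' Simple-ratio (`SR`: Ra/Rb, ordered) or normalized-difference (`ND`:
#' (Ra - Rb)/(Ra + Rb), stored in a canonical orientation with the
#' longer-wavelength band first; the reversed orientation is just a sign
#' flip that linear fits absorb).
#'
#' @param family `"SR"` or `"ND"`.
#' @param a,b Band labels (must differ).
#' @return A `wq_index` object.
#' @export
index_spec <- function(family = c("SR", "ND"), a, b) {
  family <- match.arg(family)
  if (identical(a, b)) stop("the two bands of an index must differ")
  structure(list(family = family, a = a, b = b), class = "wq_index")
}

#' @export
print.wq_index <- function(x, ...) {
  cat(index_name(x), "\n")
  invisible(x)
}

#' Human-readable index name
#' @param spec A `wq_index`.
#' @return A string such as `"B1/B4"` or `"(B4-B1)/(B4+B1)"`.
#' @export
index_name <- function(spec) {
  if (spec$family == "SR") paste0(spec$a, "/", spec$b)
  else paste0("(", spec$a, "-", spec$b, ")/(", spec$a, "+", spec$b, ")")
}

#' Enumerate all two-band indices of a band set
#'
#' All ordered simple-ratio pairs plus all unordered normalized-difference
#' pairs in canonical orientation (longer-wavelength band first): for 4
#' bands, 12 SR + 6 ND = 18 indices.
#'
#' @param bands A [band_set()].
#' @return List of `wq_index` objects.
#' @examples
#' length(enumerate_indices(band_set()))  # 18
#' @export
enumerate_indices <- function(bands = band_set()) {
  labs <- bands$label
  n <- length(labs)
  if (n < 2) stop("need at least 2 bands")
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[[length(out) + 1]] <- index_spec("SR", labs[i], labs[j])
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # canonical orientation: later (longer-wavelength) band first
      out[[length(out) + 1]] <- index_spec("ND", labs[j], labs[i])
    }
  }
  out
}

#' Compute a two-band index from reflectance spectra
#'
#' @param spectra Named reflectance vector, or a matrix/data frame with
#'   band-labelled columns (one spectrum per row).
#' @param spec A `wq_index`.
#' @return Numeric index value(s); zero denominators yield `NA` with a
#'   warning.
#' @export
compute_index <- function(spectra, spec) {
  if (is.null(dim(spectra))) {
    if (!all(c(spec$a, spec$b) %in% names(spectra))) {
      stop("spectra lack band(s) ", spec$a, " and/or ", spec$b)
    }
    ra <- spectra[[spec$a]]; rb <- spectra[[spec$b]]
  } else {
    spectra <- as.data.frame(spectra)
    if (!all(c(spec$a, spec$b) %in% names(spectra))) {
      stop("spectra lack band(s) ", spec$a, " and/or ", spec$b)
    }
    ra <- spectra[[spec$a]]; rb <- spectra[[spec$b]]
  }
  den <- if (spec$family == "SR") rb else ra + rb
  num <- if (spec$family == "SR") ra else ra - rb
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning(sum(zero), " zero-denominator value(s) in ", index_name(spec),
            " set to NA")
    den[zero] <- NA_real_
  }
  num / den
}

.fit_families <- c("linear", "exponential", "power", "logarithmic",
                   "polynomial")

# core least-squares fit of one family; returns coefficients and a
# predict function. Nonlinear families are fitted on the linearizing
# transform; statistics are always computed on the original scale.
fit_core <- function(x, y, family, degree = 2) {
  switch(family,
    linear = {
      cf <- stats::lm.fit(cbind(1, x), y)$coefficients
      list(coefficients = c(slope = unname(cf[2]),
                            intercept = unname(cf[1])),
           predict = function(z) cf[2] * z + cf[1])
    },
    exponential = { # y = a exp(b x), a > 0
      cf <- stats::lm.fit(cbind(1, x), log(y))$coefficients
      a <- exp(unname(cf[1])); b <- unname(cf[2])
      list(coefficients = c(a = a, b = b),
           predict = function(z) a * exp(b * z))
    },
    power = { # y = a x^b
      cf <- stats::lm.fit(cbind(1, log(x)), log(y))$coefficients
      a <- exp(unname(cf[1])); b <- unname(cf[2])
      list(coefficients = c(a = a, b = b),
           predict = function(z) a * z^b)
    },
    logarithmic = { # y = a + b ln x
      cf <- stats::lm.fit(cbind(1, log(x)), y)$coefficients
      a <- unname(cf[1]); b <- unname(cf[2])
      list(coefficients = c(a = a, b = b),
           predict = function(z) a + b * log(z))
    },
    polynomial = {
      X <- stats::poly(x, degree = degree, raw = TRUE)
      cf <- stats::lm.fit(cbind(1, X), y)$coefficients
      cf[is.na(cf)] <- 0
      coefs <- rev(unname(cf)) # descending powers
      names(coefs) <- paste0("c", seq(degree, 0))
      list(coefficients = coefs,
           predict = function(z) {
             out <- 0
             for (p in seq(degree, 0)) {
               out <- out + coefs[[paste0("c", p)]] * z^p
             }
             out
           })
    },
    stop("unknown fit family: ", family)
  )
}

check_fit_domain <- function(x, y, family) {
  if (family %in% c("power", "logarithmic") && any(x <= 0)) {
    stop(family, " fit requires x > 0; offending values: ",
         paste(utils::head(signif(x[x <= 0], 4), 3), collapse = ", "))
  }
  if (family %in% c("exponential", "power") && any(y <= 0)) {
    stop(family, " fit requires y > 0; offending values: ",
         paste(utils::head(signif(y[y <= 0], 4), 3), collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit one function family to index/target pairs
#'
#' Least-squares fit of one of the five families used in empirical
#' retrieval work — linear (y = sx + i), exponential (y = a e^(bx)),
#' power (y = a x^b), logarithmic (y = a + b ln x), polynomial (default
#' degree 2). Nonlinear families are fitted by their linearizing
#' transform; validation statistics are computed on the original scale.
#'
#' @param x Index values.
#' @param y Target (water-quality) values, same length.
#' @param family One of `"linear"`, `"exponential"`, `"power"`,
#'   `"logarithmic"`, `"polynomial"`.
#' @param degree Polynomial degree (default 2).
#' @param variable Optional target label stored on the model.
#' @param index Optional `wq_index` stored on the model.
#' @return A `wq_fit`: list with `family`, `coefficients`, `predict`,
#'   `stats` (calibration [summary_stats()]), `variable`, `index`,
#'   `formula`.
#' @examples
#' f <- fit_model(1:10, 2 * (1:10) + 1, "linear")
#' f$coefficients  # slope 2, intercept 1
#' @export
fit_model <- function(x, y, family = .fit_families, degree = 2,
                      variable = NULL, index = NULL) {
  family <- match.arg(family)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  min_n <- max(3, if (family == "polynomial") degree + 1 else 2)
  if (length(x) < min_n) {
    stop("need at least ", min_n, " finite pairs for a ", family, " fit")
  }
  if (stats::sd(x) == 0) stop("x is constant: rank-deficient fit")
  if (stats::sd(y) == 0) stop("y is constant: rank-deficient fit")
  check_fit_domain(x, y, family)
  core <- fit_core(x, y, family, degree)
  pred <- core$predict(x)
  structure(
    list(family = family, coefficients = core$coefficients,
         predict = core$predict,
         stats = summary_stats(y, pred),
         degree = if (family == "polynomial") degree else NULL,
         variable = variable, index = index,
         formula = fit_formula_string(family, core$coefficients)),
    class = "wq_fit"
  )
}

#' @export
print.wq_fit <- function(x, ...) {
  cat("<wq_fit> ", x$family,
      if (!is.null(x$index)) paste0(" on ", index_name(x$index)),
      ": ", x$formula, "\n", sep = "")
  invisible(x)
}

fit_formula_string <- function(family, cf) {
  sgn <- function(v) if (v < 0) paste0(" - ", signif(-v, 6)) else
    paste0(" + ", signif(v, 6))
  switch(family,
    linear = paste0("y = ", signif(cf[["slope"]], 6), "x",
                    sgn(cf[["intercept"]])),
    exponential = paste0("y = ", signif(cf[["a"]], 6), "*exp(",
                         signif(cf[["b"]], 6), "x)"),
    power = paste0("y = ", signif(cf[["a"]], 6), "*x^",
                   signif(cf[["b"]], 6)),
    logarithmic = paste0("y = ", signif(cf[["a"]], 6),
                         sgn(cf[["b"]]), "*ln(x)") ,
    polynomial = {
      p <- seq(length(cf) - 1, 0)
      terms <- paste0(signif(unname(cf), 6),
                      ifelse(p > 1, paste0("x^", p),
                             ifelse(p == 1, "x", "")))
      paste0("y = ", paste(terms, collapse = " + "))
    })
}

#' Validation statistics for observed/predicted pairs
#'
#' R-squared is the squared Pearson correlation of observed and
#' predicted; RMSE and MAE are in target units; bias is
#' mean(predicted - observed); NRMSE is 100 * RMSE / (observed range),
#' with the range taken from the observations unless overridden (for
#' instance by the full-sample range during cross-validation).
#'
#' @param observed,predicted Paired numeric vectors, length >= 2.
#' @param observed_range Optional `c(min, max)` overriding the
#'   normalization range.
#' @return One-row tibble: `r_squared`, `rmse`, `nrmse_pct`, `mae`,
#'   `bias`, `n`.
#' @export
summary_stats <- function(observed, predicted, observed_range = NULL) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 2) stop("need at least 2 finite pairs")
  err <- predicted - observed
  rmse <- sqrt(mean(err^2))
  rng <- if (is.null(observed_range)) range(observed) else observed_range
  width <- diff(rng)
  r2 <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    NA_real_ else stats::cor(observed, predicted)^2
  tibble::tibble(
    r_squared = r2,
    rmse = rmse,
    nrmse_pct = if (width > 0) 100 * rmse / width else NA_real_,
    mae = mean(abs(err)),
    bias = mean(err),
    n = length(observed)
  )
}

#' K-fold cross-validation of one index/family combination
#'
#' Seeded uniform shuffle into `k` folds as equal as possible; each fold
#' is held out once while the remainder is fitted, and held-out RMSE,
#' MAE and R-squared are averaged across folds. Bias is
#' mean(predicted - observed) pooled over all held-out predictions, and
#' NRMSE is normalized by the full-sample observed range. A pooled
#' R-squared over all held-out predictions is reported alongside the
#' fold mean (tiny folds make fold-level R-squared degenerate).
#'
#' @param x Index values.
#' @param y Target values.
#' @param family Fit family (see [fit_model()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @param degree Polynomial degree.
#' @return One-row tibble: `r_squared` (fold mean), `r_squared_pooled`,
#'   `rmse` (fold mean), `rmse_pooled`, `nrmse_pct`, `mae`, `bias`,
#'   `n`, `k_folds`.
#' @export
crossvalidate <- function(x, y, family = .fit_families, k = 10, seed = 1,
                          degree = 2) {
  family <- match.arg(family)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("n = ", n, " < k = ", k, "; reduce k")
  check_fit_domain(x, y, family)
  folds <- with_seed(seed, {
    idx <- sample.int(n)
    split(idx, rep(seq_len(k), length.out = n))
  })
  fold_rmse <- fold_mae <- fold_r2 <- numeric(k)
  pooled_pred <- pooled_obs <- numeric(0)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    core <- fit_core(x[train], y[train], family, degree)
    pred <- core$predict(x[test])
    err <- pred - y[test]
    fold_rmse[f] <- sqrt(mean(err^2))
    fold_mae[f] <- mean(abs(err))
    fold_r2[f] <- if (length(test) >= 2 && stats::sd(y[test]) > 0 &&
                        stats::sd(pred) > 0)
      stats::cor(y[test], pred)^2 else NA_real_
    pooled_pred <- c(pooled_pred, pred)
    pooled_obs <- c(pooled_obs, y[test])
  }
  width <- diff(range(y))
  tibble::tibble(
    r_squared = mean(fold_r2, na.rm = TRUE),
    r_squared_pooled = if (stats::sd(pooled_pred) > 0)
      stats::cor(pooled_obs, pooled_pred)^2 else NA_real_,
    rmse_pooled = sqrt(mean((pooled_pred - pooled_obs)^2)),
    rmse = mean(fold_rmse),
    nrmse_pct = if (width > 0) 100 * mean(fold_rmse) / width else NA_real_,
    mae = mean(fold_mae),
    bias = mean(pooled_pred - pooled_obs),
    n = n,
    k_folds = k
  )
}

#' Rank all index/family combinations for one variable
#'
#' Evaluates every enumerated two-band index crossed with every requested
#' fit family on a matchup table, cross-validating each combination, and
#' returns the combinations sorted by ascending cross-validated RMSE
#' (ties broken by higher R-squared, then by index name). This is the
#' exhaustive band-combination search that yields the "best algorithms"
#' tables of empirical retrieval studies.
#'
#' @param matchups Matchup table with band columns (`B1`..`B4`) and the
#'   target variable column.
#' @param variable Target column name (e.g. `"chl_a"`).
#' @param families Fit families to try (default all five).
#' @param k Cross-validation folds (default 10).
#' @param seed Shuffle seed.
#' @param top_n Rows in the `top` table (default 5).
#' @param degree Polynomial degree.
#' @param bands A [band_set()] describing the band columns.
#' @return A `wq_ranking`: list with `top` (best `top_n` rows), `table`
#'   (all successful combinations, sorted; columns `band_comb`,
#'   `family`, `formula`, `r2`, `rmse`, `nrmse_pct`, `mae`, `bias`,
#'   `n`, plus a `fit` list-column), `failures` (combination + message),
#'   `variable`, `k`, `seed`.
#' @export
rank_indices <- function(matchups, variable, families = .fit_families,
                         k = 10, seed = 1, top_n = 5, degree = 2,
                         bands = band_set()) {
  if (!variable %in% names(matchups)) {
    stop("matchups lack a '", variable, "' column")
  }
  y_all <- matchups[[variable]]
  specs <- enumerate_indices(bands)
  rows <- list(); fits <- list(); failures <- list()
  for (spec in specs) {
    x_all <- suppressWarnings(compute_index(matchups, spec))
    for (family in families) {
      res <- tryCatch({
        ok <- is.finite(x_all) & is.finite(y_all)
        if (sum(ok) < max(k, 3)) {
          stop("only ", sum(ok), " complete pairs")
        }
        fit <- fit_model(x_all[ok], y_all[ok], family, degree = degree,
                         variable = variable, index = spec)
        cv <- crossvalidate(x_all[ok], y_all[ok], family, k = k,
                            seed = seed, degree = degree)
        list(fit = fit, cv = cv)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          band_comb = index_name(spec), family = family,
          message = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        band_comb = index_name(spec), family = family,
        formula = res$fit$formula,
        r2 = res$cv$r_squared_pooled,
        rmse = res$cv$rmse, nrmse_pct = res$cv$nrmse_pct,
        mae = res$cv$mae, bias = res$cv$bias, n = res$cv$n)
      fits[[length(fits) + 1]] <- res$fit
    }
  }
  if (!length(rows)) {
    fl <- do.call(rbind, failures)
    stop("all index/family fits failed; first failure: ",
         fl$band_comb[1], " ", fl$family[1], ": ", fl$message[1])
  }
  tab <- do.call(rbind, rows)
  tab$fit <- fits
  ord <- order(tab$rmse, -tab$r2, tab$band_comb)
  tab <- tab[ord, ]
  structure(
    list(top = utils::head(tab, top_n), table = tab,
         failures = if (length(failures)) do.call(rbind, failures)
                    else tibble::tibble(),
         variable = variable, k = k, seed = seed),
    class = "wq_ranking"
  )
}

#' @export
print.wq_ranking <- function(x, ...) {
  cat("<wq_ranking> ", x$variable, ": ", nrow(x$table),
      " index/family combinations, k = ", x$k, "\n", sep = "")
  print(x$top[, c("band_comb", "family", "formula", "r2", "rmse",
                  "nrmse_pct", "mae", "bias")])
  invisible(x)
}
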