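# map coordinates -> pixel row/col for an axis-aligned geotransform
# (x0, dx, 0, y0, 0, dy); pixel centers at x0 + (col - 0.5) dx.
coords_to_rowcol <- function(scn, x, y) {
  gt <- scn$geotransform
  if (gt[3] != 0 || gt[5] != 0) stop("rotated geotransforms not supported")
  col <- floor((x - gt[1]) / gt[2]) + 1L
  row <- floor((y - gt[4]) / gt[6]) + 1L
  c(row = row, col = col)
}

#' Extract a region-of-interest mean spectrum around a sampling point
#'
#' Grows a square window centered on the point and returns the per-band
#' mean and standard deviation of surface reflectance over the water
#' pixels it contains. The window side is the largest whose water-pixel
#' count does not exceed the upper target, and the ROI is accepted only
#' if that count also reaches the lower target (the study protocol uses
#' ROIs of 100-150 pixels). On an all-water raster this yields a 12 x 12
#' window (144 pixels).
#'
#' @param scn A `wq_scene` in `surface_reflectance` state.
#' @param x,y Point coordinates in the scene CRS.
#' @param target_pixels Integer `c(min, max)` water-pixel count target;
#'   default `c(100, 150)`.
#' @param mask Logical water mask matrix (TRUE = water); default all
#'   water.
#' @param max_side Maximum window side length in pixels.
#' @return List with `spectrum` (named band means), `spectrum_sd`,
#'   `n_pixels`, `side`.
#' @export
extract_roi <- function(scn, x, y, target_pixels = c(100, 150),
                        mask = NULL, max_side = 31) {
  assert_state(scn, "surface_reflectance")
  d <- dim(scn$data)
  rc <- coords_to_rowcol(scn, x, y)
  if (rc["row"] < 1 || rc["row"] > d[1] || rc["col"] < 1 || rc["col"] > d[2]) {
    stop("point (", x, ", ", y, ") falls outside the raster extent")
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  window_idx <- function(side) {
    lo <- floor((side - 1) / 2)
    hi <- floor(side / 2)
    rows <- max(1, rc["row"] - lo):min(d[1], rc["row"] + hi)
    cols <- max(1, rc["col"] - lo):min(d[2], rc["col"] + hi)
    list(rows = rows, cols = cols)
  }
  best <- NULL
  for (side in seq_len(max_side)) {
    w <- window_idx(side)
    count <- sum(mask[w$rows, w$cols])
    if (count <= target_pixels[2]) best <- list(side = side, w = w,
                                                count = count)
    else break
  }
  if (is.null(best) || best$count < target_pixels[1]) {
    stop("cannot reach ", target_pixels[1], " water pixels without ",
         "exceeding ", target_pixels[2], " (best window had ",
         if (is.null(best)) "too many" else best$count, ")")
  }
  nb <- dim(scn$data)[3]
  labs <- scn$band_set$label
  m <- numeric(nb); sdv <- numeric(nb)
  sel <- mask[best$w$rows, best$w$cols]
  for (b in seq_len(nb)) {
    vals <- scn$data[best$w$rows, best$w$cols, b][sel]
    vals <- vals[!is.na(vals)]
    m[b] <- mean(vals)
    sdv[b] <- stats::sd(vals)
  }
  names(m) <- labs; names(sdv) <- labs
  list(spectrum = m, spectrum_sd = sdv, n_pixels = best$count,
       side = best$side)
}

#' Build the matchup database
#'
#' Pairs each field sample with the nearest-in-time scene within the
#' allowed lag (default 3 days; equidistant scenes break toward the
#' earlier one) and, when sampling-point coordinates are given, extracts
#' the ROI mean spectrum at each point. Unpaired samples are reported.
#'
#' @param scenes List of `wq_scene` objects in `surface_reflectance`
#'   state, each with a `date`.
#' @param samples A `wq_field_samples` tibble (or any data frame with
#'   `point_id`, `campaign_date` and the variable columns).
#' @param points Optional data frame `point_id, x, y` in the scene CRS;
#'   when given, ROI spectra are extracted.
#' @param max_lag_days Maximum |image date - sample date| in days
#'   (default 3).
#' @param masks Optional list of logical water masks, one per scene.
#' @param target_pixels ROI pixel-count target passed to
#'   [extract_roi()].
#' @return List with `matchups` (tibble: ids, dates, `lag_days`,
#'   `n_pixels`, band means `B1`..`B4`, band sds `B1_sd`.., and the
#'   sample variables) and `unpaired` (tibble of excluded samples with a
#'   `reason`).
#' @export
build_matchups <- function(scenes, samples, points = NULL,
                           max_lag_days = 3, masks = NULL,
                           target_pixels = c(100, 150)) {
  if (length(scenes) == 0) stop("empty scene list")
  if (max_lag_days < 0) stop("max_lag_days must be >= 0")
  scene_dates <- as.Date(vapply(scenes, function(s) {
    if (is.null(s$date)) stop("every scene needs a date")
    as.character(s$date)
  }, character(1)))
  labs <- scenes[[1]]$band_set$label
  rows <- list(); unpaired <- list()
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    lags <- as.integer(abs(difftime(scene_dates, smp$campaign_date,
                                    units = "days")))
    # nearest in time; ties toward the earlier scene
    ord <- order(lags, scene_dates)
    j <- ord[1]
    if (lags[j] > max_lag_days) {
      unpaired[[length(unpaired) + 1]] <- tibble::tibble(
        point_id = smp$point_id, sample_date = smp$campaign_date,
        reason = sprintf("nearest scene lag %d d exceeds %d d",
                         lags[j], max_lag_days))
      next
    }
    rec <- tibble::tibble(
      point_id = smp$point_id,
      image_date = scene_dates[j], sample_date = smp$campaign_date,
      lag_days = lags[j]
    )
    if (!is.null(points)) {
      pt <- points[points$point_id == smp$point_id, , drop = FALSE]
      if (nrow(pt) != 1) {
        unpaired[[length(unpaired) + 1]] <- tibble::tibble(
          point_id = smp$point_id, sample_date = smp$campaign_date,
          reason = "no coordinates for point")
        next
      }
      roi <- extract_roi(scenes[[j]], pt$x, pt$y,
                         target_pixels = target_pixels,
                         mask = if (is.null(masks)) NULL else masks[[j]])
      for (b in seq_along(labs)) {
        rec[[labs[b]]] <- unname(roi$spectrum[b])
        rec[[paste0(labs[b], "_sd")]] <- unname(roi$spectrum_sd[b])
      }
      rec$n_pixels <- roi$n_pixels
    }
    for (v in intersect(.wq_variables, names(samples))) rec[[v]] <- smp[[v]]
    rows[[length(rows) + 1]] <- rec
  }
  list(
    matchups = if (length(rows)) do.call(rbind, rows) else tibble::tibble(),
    unpaired = if (length(unpaired)) do.call(rbind, unpaired)
               else tibble::tibble()
  )
}

#' Test spectral stability between two dates
#'
#' Student's t-test comparing water spectra observed at two dates, used
#' to justify a non-zero matchup lag: if the spectra do not differ
#' significantly the water is considered stable over the window. The
#' default is a paired two-sided test on the per-band differences; a
#' pooled two-sample test is available.
#'
#' @param spectra_a,spectra_b Paired reflectance sets (vectors or
#'   matrices flattened in the same order).
#' @param alpha Significance level (default 0.05); stable iff
#'   p >= alpha.
#' @param mode `"paired"` (default) or `"pooled"` (two-sample).
#' @return List with `statistic`, `p_value`, `stable`, `mode`, `n`.
#' @export
spectral_stability_test <- function(spectra_a, spectra_b, alpha = 0.05,
                                    mode = c("paired", "pooled")) {
  mode <- match.arg(mode)
  a <- as.vector(as.matrix(spectra_a))
  b <- as.vector(as.matrix(spectra_b))
  if (mode == "paired" && length(a) != length(b)) {
    stop("paired mode needs equal-length spectra")
  }
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per set")
  degenerate <- function(delta) {
    # zero-variance differences: identical spectra are stable (t = 0);
    # a constant nonzero shift is unstable by the p = 0 convention
    if (delta == 0) {
      list(statistic = 0, p_value = 1, stable = TRUE, mode = mode,
           n = length(a))
    } else {
      list(statistic = sign(delta) * Inf, p_value = 0, stable = FALSE,
           mode = mode, n = length(a))
    }
  }
  if (mode == "paired") {
    dif <- a - b
    if (stats::sd(dif) == 0) return(degenerate(mean(dif)))
    tt <- tryCatch(stats::t.test(a, b, paired = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) return(degenerate(mean(dif)))
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(degenerate(mean(a) - mean(b)))
    }
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) return(degenerate(mean(a) - mean(b)))
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       stable = tt$p.value >= alpha, mode = mode, n = length(a))
}

#' Normality-gated cross-correlation of water-quality variables
#'
#' For every variable pair, uses pairwise-complete observations, tests
#' both margins for normality (Shapiro-Wilk) and computes the Pearson
#' correlation when both pass, otherwise Spearman — mirroring the
#' standard practice of falling back to the non-parametric coefficient
#' for non-normal limnological variables.
#'
#' @param samples Data frame with columns among `chl_a`, `sdd`, `tsm`,
#'   `pim`, `pom`.
#' @param alpha_normality Shapiro-Wilk significance level (default
#'   0.05).
#' @param variables Variables to correlate (default all five present).
#' @return A `wq_cor_matrix`: list of matrices `r` (coefficients,
#'   symmetric, unit diagonal), `n` (pairwise-complete counts),
#'   `p_value`, and `method` ("pearson"/"spearman"); plus `table`, a
#'   tidy tibble of the upper triangle.
#' @export
cross_correlate <- function(samples, alpha_normality = 0.05,
                            variables = intersect(.wq_variables,
                                                  names(samples))) {
  nv <- length(variables)
  if (nv < 2) stop("need at least 2 variables")
  r <- matrix(NA_real_, nv, nv, dimnames = list(variables, variables))
  nmat <- matrix(0L, nv, nv, dimnames = dimnames(r))
  pmat <- r
  meth <- matrix(NA_character_, nv, nv, dimnames = dimnames(r))
  diag(r) <- 1
  rows <- list()
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      x <- samples[[variables[i]]]
      y <- samples[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
        meth[i, j] <- meth[j, i] <- "none"
        next
      }
      normal <- tryCatch(
        stats::shapiro.test(x)$p.value >= alpha_normality &&
          stats::shapiro.test(y)$p.value >= alpha_normality,
        error = function(e) FALSE)
      method <- if (normal) "pearson" else "spearman"
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
      meth[i, j] <- meth[j, i] <- method
      rows[[length(rows) + 1]] <- tibble::tibble(
        var1 = variables[i], var2 = variables[j],
        coefficient = unname(ct$estimate), n = n, method = method,
        p_value = ct$p.value)
    }
  }
  structure(
    list(r = r, n = nmat, p_value = pmat, method = meth,
         table = if (length(rows)) do.call(rbind, rows)
                 else tibble::tibble()),
    class = "wq_cor_matrix"
  )
}

#' @export
print.wq_cor_matrix <- function(x, ...) {
  cat("<wq_cor_matrix> coefficients (pairwise n in parentheses):\n")
  print(round(x$r, 3))
  invisible(x)
}
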