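#' Define a multispectral band set
#'
#' A band set holds the spectral band labels, wavelength ranges and spatial
#' resolution of a sensor. The default is the four-band configuration of a
#' NAOMI-class high-resolution imager: blue, green, red and NIR at 2.8 m.
#'
#' @param labels Character vector of band labels (default `B1`..`B4`).
#' @param wl_min,wl_max Numeric vectors of band lower/upper wavelength
#'   bounds in nm. Ranges must be ascending and non-overlapping.
#' @param resolution_m Spatial resolution in metres (single value).
#'
#' @return An object of class `wq_bandset`: a tibble with columns
#'   `label`, `wl_min_nm`, `wl_max_nm`, `resolution_m`.
#' @examples
#' band_set()
#' @export
band_set <- function(labels = c("B1", "B2", "B3", "B4"),
                     wl_min = c(450, 530, 630, 752),
                     wl_max = c(520, 590, 700, 885),
                     resolution_m = 2.8) {
  n <- length(labels)
  stopifnot(length(wl_min) == n, length(wl_max) == n, n >= 2)
  if (anyDuplicated(labels)) {
    stop("duplicate band labels in band set: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  }
  if (any(wl_max <= wl_min)) {
    stop("each band must have wl_max > wl_min")
  }
  if (is.unsorted(wl_min, strictly = TRUE) ||
      any(wl_min[-1] < wl_max[-n])) {
    stop("band wavelength ranges must be ascending and non-overlapping")
  }
  out <- tibble::tibble(
    label = as.character(labels),
    wl_min_nm = as.numeric(wl_min),
    wl_max_nm = as.numeric(wl_max),
    resolution_m = resolution_m
  )
  class(out) <- c("wq_bandset", class(out))
  out
}

#' @export
print.wq_bandset <- function(x, ...) {
  cat("<wq_bandset> ", nrow(x), " bands, ",
      x$resolution_m[1], " m resolution\n", sep = "")
  NextMethod()
}

n_bands <- function(band_set) nrow(band_set)

band_index <- function(band_set, label) {
  i <- match(label, band_set$label)
  if (anyNA(i)) {
    stop("band(s) not in band set: ",
         paste(label[is.na(i)], collapse = ", "))
  }
  i
}
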