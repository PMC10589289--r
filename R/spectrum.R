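#' Optical spectrum container
#'
#' Construct a `spectrum` object: a wavelength grid with one value per grid
#' point and a `kind` saying what the values are. This is the common currency
#' of the spectral functions — absorbance decomposition, reflectance dip
#' detection and emission summaries all consume and return it.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing. Instrument data typically come on a 1-nm grid.
#' @param values Numeric vector, same length as `wavelengths`. Absorbance is
#'   dimensionless, reflectance a fraction, emission in
#'   nmol photons m^-2 s^-1.
#' @param kind One of `"absorbance"`, `"reflectance"`, `"emission"`.
#' @param meta Named list of metadata (sample id, species, date; for emission
#'   spectra `excitation_nm` and `excitation_ru` record the excitation band).
#'
#' @return An object of class `spectrum`.
#' @examples
#' wl <- 400:800
#' s <- spectrum(wl, exp(-((wl - 676) / 15)^2), kind = "absorbance")
#' spec_value_at(s, 676)
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("absorbance", "reflectance", "emission"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least two grid points", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (kind != "emission" && any(!is.finite(values))) {
    stop("absorbance/reflectance values must be finite", call. = FALSE)
  }
  if (!is.list(meta)) stop("meta must be a list", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, values = values, kind = kind, meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n",
              x$kind, length(x$wavelengths), rng[1], rng[2]))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta, use.names = FALSE),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Evaluate a spectrum at arbitrary wavelengths
#'
#' Linear interpolation between grid points; exact at grid points. Wavelength
#' windows in this package are inclusive and anchor wavelengths off-grid are
#' interpolated rather than snapped.
#'
#' @param s A [spectrum()].
#' @param wl Wavelengths (nm) at which to evaluate; must lie within the grid.
#' @return Numeric vector of interpolated values.
#' @export
spec_value_at <- function(s, wl) {
  stopifnot(is_spectrum(s))
  rng <- range(s$wavelengths)
  if (any(wl < rng[1] | wl > rng[2])) {
    stop(sprintf("wavelength outside grid [%g, %g] nm", rng[1], rng[2]),
         call. = FALSE)
  }
  stats::approx(s$wavelengths, s$values, xout = wl, method = "linear",
                ties = "ordered")$y
}

# Error unless two spectra share an identical wavelength grid.
check_common_grid <- function(a, b) {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(a$wavelengths != b$wavelengths)) {
    stop("spectra are not on a common wavelength grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Moving-window polynomial smoother
#'
#' Savitzky-Golay-style smoothing for noisy instrument spectra: an
#' odd-length window is slid across the grid and a least-squares polynomial
#' evaluated at its centre. Off by default everywhere in the pipeline; peak
#' detection on clean spectra is more accurate without it.
#'
#' @param s A [spectrum()].
#' @param window Odd window length in grid points (default 7).
#' @param order Polynomial order (default 2); must be `< window`.
#' @return A smoothed [spectrum()].
#' @export
smooth_spectrum <- function(s, window = 7L, order = 2L) {
  stopifnot(is_spectrum(s))
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  if (order >= window) stop("order must be smaller than window", call. = FALSE)
  n <- length(s$values)
  if (n < window) stop("spectrum shorter than smoothing window", call. = FALSE)
  half <- window %/% 2L
  # convolution weights for the central point of an LS polynomial fit
  x <- seq(-half, half)
  X <- outer(x, 0:order, `^`)
  w <- (X %*% solve(crossprod(X), diag(order + 1L)[, 1L]))[, 1L]
  v <- stats::filter(s$values, rev(w), sides = 2)
  # keep raw values at the edges where the window does not fit
  v[is.na(v)] <- s$values[is.na(v)]
  spectrum(s$wavelengths, as.numeric(v), kind = s$kind, meta = s$meta)
}
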