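#' Excitation light setting of the PAM mini-spectrometer
#'
#' The instrument excites with a blue LED (peak 452 nm, intensity 200
#' relative units by default) or a green LED (peak 525 nm, 600 relative
#' units). Green light is funneled by phycobiliproteins to PS II; blue light
#' also excites the Chl-a of PS I, which is why comparing the two reveals the
#' Chl-a partitioning.
#'
#' @param color `"blue"` or `"green"`.
#' @param peak Excitation peak, nm (defaults 452 blue / 525 green).
#' @param intensity Instrument intensity in relative units; `> 0`
#'   (defaults 200 blue / 600 green).
#' @return An `excitation_setting` object.
#' @export
excitation_setting <- function(color = c("blue", "green"),
                               peak = NULL, intensity = NULL) {
  color <- match.arg(color)
  peak <- peak %||% if (color == "blue") 452 else 525
  intensity <- intensity %||% if (color == "blue") 200 else 600
  if (!is.finite(intensity) || intensity <= 0) {
    stop("intensity must be > 0", call. = FALSE)
  }
  structure(list(color = color, peak = peak, intensity = intensity),
            class = "excitation_setting")
}

#' Summarise a chlorophyll-a emission spectrum
#'
#' Detects the global maximum in 670-700 nm (quadratic-refined) as the PS II
#' Chl-a emission peak, and reads the 730-nm vibrational shoulder by
#' interpolation. A flat or absent peak — observed for *P. palmata* in
#' January under blue excitation — yields `no_peak = TRUE` with the detected
#' wavelength outside the valid 680-690 nm band, not an error.
#'
#' @param s An emission [spectrum()] covering 600-850 nm; excitation
#'   metadata (`excitation_nm`, `excitation_ru`) is carried through when
#'   present.
#' @param peak_window Search window for the 685-nm peak (default
#'   `c(670, 700)`).
#' @return An `emission_summary`: `peak685` (value at the detected peak),
#'   `shoulder730`, `peak_wavelength`, `no_peak`, `excitation`.
#' @export
summarize_emission <- function(s, peak_window = c(670, 700)) {
  stopifnot(is_spectrum(s))
  if (s$kind != "emission") {
    stop("summarize_emission expects an emission spectrum", call. = FALSE)
  }
  if (min(s$wavelengths) > 600 || max(s$wavelengths) < 850) {
    stop("emission grid must cover 600-850 nm", call. = FALSE)
  }
  exc <- if (!is.null(s$meta$excitation_nm) &&
             !is.null(s$meta$excitation_ru)) {
    color <- if (as.numeric(s$meta$excitation_nm) < 500) "blue" else "green"
    excitation_setting(color,
                       peak = as.numeric(s$meta$excitation_nm),
                       intensity = as.numeric(s$meta$excitation_ru))
  } else {
    NULL
  }
  pk <- tryCatch(find_red_peak(s, peak_window), error = function(e) NULL)
  if (is.null(pk)) {
    # no interior maximum: report the largest value's wavelength, flagged
    idx <- which(s$wavelengths >= peak_window[1] &
                   s$wavelengths <= peak_window[2])
    i <- idx[which.max(s$values[idx])]
    wl <- s$wavelengths[i]
    val <- s$values[i]
    no_peak <- TRUE
  } else {
    wl <- as.numeric(pk)
    val <- spec_value_at(s, wl)
    no_peak <- wl < 680 || wl > 690
  }
  structure(list(peak685 = val,
                 shoulder730 = spec_value_at(s, 730),
                 peak_wavelength = wl,
                 no_peak = no_peak,
                 excitation = exc),
            class = "emission_summary")
}

#' @export
print.emission_summary <- function(x, ...) {
  cat(sprintf("<emission_summary: peak %.4g at %.1f nm%s, shoulder730 %.4g>\n",
              x$peak685, x$peak_wavelength,
              if (x$no_peak) " (no valid 685-nm peak)" else "",
              x$shoulder730))
  invisible(x)
}

#' Green-to-blue chlorophyll-a emission ratio
#'
#' Ratio of the 685-nm emission peaks under green and under blue excitation,
#' as displayed by the instrument (no intensity adjustment). With
#' `use_integral = TRUE` the 670-750 nm trapezoid band integrals are used
#' instead of peak values, for sensitivity analysis.
#'
#' @param green,blue Either `emission_summary` objects or emission
#'   [spectrum()] objects (summarised internally).
#' @param use_integral Use band integrals instead of peak values.
#' @return The raw green:blue ratio.
#' @export
green_blue_ratio <- function(green, blue, use_integral = FALSE) {
  if (use_integral) {
    gi <- emission_band_integral(green)
    bi <- emission_band_integral(blue)
    if (bi <= 0) stop("undefined ratio: blue band integral is 0",
                      call. = FALSE)
    return(gi / bi)
  }
  g <- if (is_spectrum(green)) summarize_emission(green) else green
  b <- if (is_spectrum(blue)) summarize_emission(blue) else blue
  stopifnot(inherits(g, "emission_summary"), inherits(b, "emission_summary"))
  if (b$peak685 <= 0) {
    stop("undefined ratio: blue peak685 is 0", call. = FALSE)
  }
  g$peak685 / b$peak685
}

# Trapezoid integral of an emission spectrum over 670-750 nm.
emission_band_integral <- function(s, window = c(670, 750)) {
  stopifnot(is_spectrum(s))
  keep <- s$wavelengths >= window[1] & s$wavelengths <= window[2]
  x <- s$wavelengths[keep]
  y <- s$values[keep]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Adjust an emission ratio for unequal excitation intensities
#'
#' The raw green:blue ratio reflects both pigment physiology and the
#' instrument's excitation settings. Dividing by the intensity ratio
#' (600/200 = 3 with the default settings) puts the two channels on the same
#' energy-output footing; a raw 9-10x green excess then becomes the ~3x
#' physiological excess of energy transfer to PS II.
#'
#' @param raw_ratio Raw green:blue ratio from [green_blue_ratio()].
#' @param green_setting,blue_setting [excitation_setting()] objects.
#' @return The adjusted ratio, with attribute `note` recording the
#'   interpretation of the adjustment.
#' @examples
#' adjust_for_excitation(9) # 3
#' @export
adjust_for_excitation <- function(raw_ratio,
                                  green_setting = excitation_setting("green"),
                                  blue_setting = excitation_setting("blue")) {
  stopifnot(inherits(green_setting, "excitation_setting"),
            inherits(blue_setting, "excitation_setting"))
  if (green_setting$intensity <= 0 || blue_setting$intensity <= 0) {
    stop("excitation intensities must be > 0", call. = FALSE)
  }
  structure(raw_ratio / (green_setting$intensity / blue_setting$intensity),
            note = paste("green emission scaled down by the excitation",
                         "intensity ratio",
                         sprintf("%g/%g", green_setting$intensity,
                                 blue_setting$intensity)))
}

#' Compare absorbance- and emission-based PS II Chl-a fractions
#'
#' The PS II fraction can be estimated two ways: from the absorbance
#' decomposition (the red-peak ratio) and from the interpreted emission
#' ratio. No default mapping from the adjusted emission ratio to a fraction
#' is shipped — the emission-based fraction must be supplied, either
#' directly or through a user calibration function applied to the adjusted
#' ratio.
#'
#' @param absorbance_fraction PS II fraction from
#'   [psii_fraction_at_red()], in `[0, 1]`.
#' @param emission_fraction PS II fraction inferred from emission, in
#'   `[0, 1]`; or `NULL` if `adjusted_ratio` and `calibration` are given.
#' @param adjusted_ratio Optional adjusted green:blue ratio.
#' @param calibration Optional function mapping an adjusted ratio to a
#'   fraction.
#' @return A list with both fractions and `difference_pp`, their signed
#'   difference in percentage points (absorbance minus emission).
#' @export
compare_psii_fraction_estimates <- function(absorbance_fraction,
                                            emission_fraction = NULL,
                                            adjusted_ratio = NULL,
                                            calibration = NULL) {
  if (is.null(emission_fraction)) {
    if (is.null(adjusted_ratio) || is.null(calibration)) {
      stop(paste("supply emission_fraction, or adjusted_ratio together",
                 "with a calibration function"), call. = FALSE)
    }
    emission_fraction <- calibration(adjusted_ratio)
  }
  for (f in c(absorbance_fraction, emission_fraction)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      stop("fractions must be in [0, 1]", call. = FALSE)
    }
  }
  list(absorbance_fraction = absorbance_fraction,
       emission_fraction = emission_fraction,
       difference_pp = 100 * (absorbance_fraction - emission_fraction))
}
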