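#' Gaussian pigment band
#'
#' A single pigment absorption (or emission) feature parameterised by its
#' centre wavelength, full width at half maximum and peak amplitude. Sums of
#' such bands are the building blocks of the synthetic spectra: chlorophylls
#' absorb in the blue (Soret, 400-500 nm) and red (600-700 nm), the
#' phycobiliprotein phycoerythrin around 495/545 nm.
#'
#' @param center Centre wavelength, nm.
#' @param fwhm Full width at half maximum, nm; must be positive.
#' @param amplitude Peak height (dimensionless absorbance, or emission flux
#'   for emission bands); must be non-negative.
#' @return A `band` object (named list).
#' @export
band <- function(center, fwhm, amplitude) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("amplitude must be >= 0", call. = FALSE)
  }
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude),
            class = "band")
}

#' Evaluate a Gaussian band on a wavelength grid
#'
#' `value(center) = amplitude` and `value(center +/- fwhm/2) = amplitude/2`;
#' the band is symmetric about its centre. The integral of the continuous
#' band is `amplitude * fwhm * sqrt(pi / (4 log 2))` (~ 1.0645 * amp * fwhm).
#'
#' @param b A [band()].
#' @param grid Ascending wavelength grid, nm (1-nm spacing is typical).
#' @param kind Spectrum kind for the result (default `"absorbance"`).
#' @return A [spectrum()] with the band evaluated on `grid`.
#' @export
gaussian_band <- function(b, grid, kind = "absorbance") {
  stopifnot(inherits(b, "band"))
  if (b$center < min(grid) || b$center > max(grid)) {
    stop(sprintf("band center %g nm outside grid [%g, %g]",
                 b$center, min(grid), max(grid)), call. = FALSE)
  }
  v <- b$amplitude * exp(-4 * log(2) * (grid - b$center)^2 / b$fwhm^2)
  spectrum(grid, v, kind = kind)
}

sum_bands <- function(bands, grid, kind = "absorbance") {
  v <- rep(0, length(grid))
  for (b in bands) v <- v + gaussian_band(b, grid, kind)$values
  spectrum(grid, v, kind = kind)
}

#' Pigment-band profile of a phycobiliprotein-containing red alga
#'
#' Describes the absorption bands assigned to the fluorescent fraction
#' (LHC II + PS II: phycoerythrin at 495 nm with a 545-nm shoulder, a blue
#' Soret band, and a chlorophyll-a red band at 676 nm) and to the
#' non-fluorescent fraction (LHC I + PS I: a Soret band and a Chl-a red band
#' at 681 nm). `psii_red_fraction` sets how the total red-peak amplitude is
#' split between the two red Chl-a bands: the PS II band gets weight `w` and
#' the PS I band `1 - w`. The default 0.40 matches the partitioning observed
#' for *Palmaria palmata* by absorbance decomposition.
#'
#' @param psii_red_fraction Fraction in `[0, 1]` of red-peak amplitude in the
#'   PS II band (default 0.40).
#' @param red_center_psii,red_center_psi Red Chl-a band centres, nm
#'   (defaults 676 and 681).
#' @param red_fwhm Red-band full width at half maximum, nm (default 24).
#' @param red_amplitude Combined red-band peak amplitude (default 1).
#' @param pe_centers Phycoerythrin peak and shoulder centres, nm (default
#'   `c(495, 545)`; some instruments resolve them nearer 540/570).
#' @return A `species_profile` object with `psii_bands`, `psi_bands` and
#'   `psii_red_fraction` fields.
#' @export
species_profile <- function(psii_red_fraction = 0.40,
                            red_center_psii = 676,
                            red_center_psi = 681,
                            red_fwhm = 24,
                            red_amplitude = 1,
                            pe_centers = c(495, 545)) {
  if (psii_red_fraction < 0 || psii_red_fraction > 1) {
    stop("psii_red_fraction must be in [0, 1]", call. = FALSE)
  }
  psii <- list(
    band(pe_centers[1], fwhm = 30, amplitude = 1.0),   # PE main peak
    band(pe_centers[2], fwhm = 35, amplitude = 0.65),  # PE shoulder
    band(435, fwhm = 40, amplitude = 0.45),            # Chl a Soret (PS II)
    band(red_center_psii, fwhm = red_fwhm,
         amplitude = psii_red_fraction * red_amplitude)
  )
  psi <- list(
    band(437, fwhm = 40, amplitude = 0.35),            # Chl a Soret (PS I)
    band(red_center_psi, fwhm = red_fwhm,
         amplitude = (1 - psii_red_fraction) * red_amplitude)
  )
  structure(list(psii_bands = psii, psi_bands = psi,
                 psii_red_fraction = psii_red_fraction),
            class = "species_profile")
}

#' Synthetic red-algal absorbance fixture with known ground truth
#'
#' Builds the three spectra the absorbance decomposition operates on: the
#' whole-tissue total absorbance, its true PS II (LHC II + PS II) component,
#' and the true PS I (LHC I + PS I) component, with `total = psii + psi` at
#' every grid point by construction. A fourth spectrum emulates the
#' water-soluble phycobiliprotein extract: the PS II component multiplied by
#' an arbitrary dilution factor, which the phycoerythrin-peak normalization
#' step must undo.
#'
#' @param profile A [species_profile()].
#' @param grid Wavelength grid, nm (default `400:800`).
#' @param dilution Positive factor applied to the extract copy (default 0.5;
#'   real extracts are diluted relative to tissue).
#' @param baseline Constant absorbance offset added to total and extract to
#'   exercise the 800-nm baseline correction (default 0.05).
#' @return A list with `total`, `apsii_true`, `psi_true`, `extract`
#'   ([spectrum()] objects) and `truth` (a list recording
#'   `psii_red_fraction`, band centres and the dilution factor).
#' @export
make_palmaria_spectra <- function(profile = species_profile(),
                                  grid = 400:800,
                                  dilution = 0.5,
                                  baseline = 0.05) {
  stopifnot(inherits(profile, "species_profile"))
  if (length(profile$psii_bands) == 0L || length(profile$psi_bands) == 0L) {
    stop("profile band lists must be non-empty", call. = FALSE)
  }
  if (!is.finite(dilution) || dilution <= 0) {
    stop("dilution must be > 0", call. = FALSE)
  }
  apsii <- sum_bands(profile$psii_bands, grid)
  psi <- sum_bands(profile$psi_bands, grid)
  total <- spectrum(grid, apsii$values + psi$values, kind = "absorbance",
                    meta = list(species = "Palmaria palmata",
                                synthetic = "true"))
  total$values <- total$values + baseline
  extract <- spectrum(grid, apsii$values * dilution + baseline * dilution,
                      kind = "absorbance",
                      meta = list(species = "Palmaria palmata",
                                  fraction = "LHCII+PSII extract",
                                  synthetic = "true"))
  red_centers <- c(
    psii = profile$psii_bands[[length(profile$psii_bands)]]$center,
    psi = profile$psi_bands[[length(profile$psi_bands)]]$center
  )
  list(
    total = total,
    apsii_true = apsii,
    psi_true = psi,
    extract = extract,
    truth = list(psii_red_fraction = profile$psii_red_fraction,
                 red_center_psii = unname(red_centers["psii"]),
                 red_center_psi = unname(red_centers["psi"]),
                 dilution = dilution,
                 baseline = baseline)
  )
}

#' Synthetic chlorophyll-a emission spectrum
#'
#' Two Gaussian emission bands: the PS II Chl-a peak at 685 nm (fwhm 25 nm)
#' and its vibrational shoulder at 730 nm (fwhm 50 nm, amplitude
#' `shoulder_ratio * peak685`). Metadata records the excitation band (blue
#' LED peaking at 452 nm at 200 relative units, or green at 525 nm at 600
#' relative units, matching the PAM mini-spectrometer settings).
#'
#' @param excitation `"blue"` or `"green"`.
#' @param peak685 Peak emission at 685 nm, nmol photons m^-2 s^-1; >= 0.
#' @param shoulder_ratio Amplitude of the 730-nm band relative to the 685-nm
#'   band (default 0.4, a fixture convention — instruments report shape only).
#' @param noise_sd Additive Gaussian noise sd (default 0); must be >= 0.
#' @param seed Integer seed for the noise; `NULL` leaves the RNG alone.
#' @param grid Wavelength grid, nm (default `600:850`).
#' @return An emission [spectrum()].
#' @export
make_emission_spectrum <- function(excitation = c("green", "blue"),
                                   peak685,
                                   shoulder_ratio = 0.4,
                                   noise_sd = 0,
                                   seed = NULL,
                                   grid = 600:850) {
  excitation <- match.arg(excitation)
  if (!is.finite(peak685) || peak685 < 0) {
    stop("peak685 must be >= 0", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  v <- peak685 * exp(-4 * log(2) * (grid - 685)^2 / 25^2) +
    shoulder_ratio * peak685 * exp(-4 * log(2) * (grid - 730)^2 / 50^2)
  if (noise_sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(grid), sd = noise_sd))
  }
  setting <- if (excitation == "blue") c(452, 200) else c(525, 600)
  spectrum(grid, v, kind = "emission",
           meta = list(excitation = excitation,
                       excitation_nm = setting[1],
                       excitation_ru = setting[2],
                       synthetic = "true"))
}

#' Configuration for a simulated rapid light curve
#'
#' @param alpha Initial slope of the rETR-irradiance curve (> 0).
#' @param E_K Light saturation parameter, umol photons m^-2 s^-1 (> 0).
#' @param irradiances Actinic irradiance steps, umol photons m^-2 s^-1;
#'   non-negative and strictly increasing. The default is the 13-step
#'   Diving-PAM protocol from 0 (dark) to 445.
#' @param F0_dark,Fm_dark Dark-acclimated minimum and maximum fluorescence,
#'   mV; `0 < F0_dark < Fm_dark`.
#' @param noise_sd Additive Gaussian noise sd on the fluorescence readings,
#'   mV (default 0).
#' @param seed Integer seed for the noise.
#' @return An `rlc_sim_config` object.
#' @export
rlc_sim_config <- function(alpha = 0.30, E_K = 50,
                           irradiances = c(0, 7, 14, 20, 27, 38, 56, 85,
                                           125, 186, 243, 341, 445),
                           F0_dark = 150, Fm_dark = 500,
                           noise_sd = 0, seed = NULL) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(E_K) || E_K <= 0) stop("E_K must be > 0", call. = FALSE)
  if (any(irradiances < 0) || any(diff(irradiances) <= 0)) {
    stop("irradiances must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (!(F0_dark > 0 && F0_dark < Fm_dark)) {
    stop("need 0 < F0_dark < Fm_dark", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(alpha = alpha, E_K = E_K, irradiances = irradiances,
                 F0_dark = F0_dark, Fm_dark = Fm_dark,
                 noise_sd = noise_sd, seed = seed),
            class = "rlc_sim_config")
}

#' Simulate a rapid light curve with known Webb parameters
#'
#' Generates fluorescence readings whose derived rETR follows the Webb
#' saturating exponential exactly (before noise):
#' `rETR(E) = alpha * E_K * (1 - exp(-E / E_K))`, so the operational yield is
#' `phi'(E) = rETR(E) / E`. Maximal fluorescence under actinic light declines
#' with a hyperbolic quenching model `F'_m(E) = Fm_dark / (1 + E / (2 E_K))`
#' — the quenching shape is a simulation convenience; the fitted quantities
#' depend only on `phi'`, which is Webb-consistent regardless. `F` is then
#' `F'_m (1 - phi')`. Gaussian noise of sd `noise_sd` is added to both `F`
#' and `F'_m`. The dark step stores `F0_dark` and `Fm_dark` unchanged.
#'
#' @param config An [rlc_sim_config()].
#' @return An [rlc_record()] with a `truth` attribute carrying the simulated
#'   `alpha` and `E_K`.
#' @export
simulate_rlc <- function(config = rlc_sim_config()) {
  stopifnot(inherits(config, "rlc_sim_config"))
  E <- config$irradiances[config$irradiances > 0]
  retr <- config$alpha * config$E_K * (1 - exp(-E / config$E_K))
  phi <- retr / E
  if (any(phi > 1)) {
    stop("config implies phi'(E) > 1: alpha too large for these irradiances",
         call. = FALSE)
  }
  fm_prime <- config$Fm_dark / (1 + E / (2 * config$E_K))
  f <- fm_prime * (1 - phi)
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed,
                       stats::rnorm(2 * length(E), sd = config$noise_sd))
    f <- f + noise[seq_along(E)]
    fm_prime <- fm_prime + noise[length(E) + seq_along(E)]
  }
  rec <- rlc_record(
    dark = dark_reading(config$F0_dark, config$Fm_dark),
    steps = data.frame(E = E, F = f, Fm_prime = fm_prime),
    meta = list(synthetic = "true")
  )
  attr(rec, "truth") <- list(alpha = config$alpha, E_K = config$E_K)
  rec
}

# Printed approximate pigment means (ug pigment per g wet weight) by
# species x tissue x season. Cells the source figures leave unreported are
# filled with values consistent with the stated trends (see vignette).
pigment_means <- function() {
  rbind(
    data.frame(species = "Ulva sp.", tissue = "new",
               season = rep(c("January", "October"), each = 6),
               pigment = rep(c("Chl a", "Chl b", "Lut", "Neo", "Viola",
                               "be-Car"), 2),
               mean = c(2500, 1000, 350, 80, 112, 0,
                        1000, 400, 150, 40, 50, 50)),
    data.frame(species = "P. palmata",
               tissue = rep(rep(c("new", "old"), each = 3), 2),
               season = rep(c("January", "October"), each = 6),
               pigment = rep(c("Chl a", "Lut", "bb-Car"), 4),
               mean = c(350, 75, 4, 45, 10, 0,
                        150, 30, 10, 100, 20, 5)),
    data.frame(species = "A. esculenta",
               tissue = rep(rep(c("new", "old"), each = 4), 2),
               season = rep(c("January", "October"), each = 8),
               pigment = rep(c("Chl a", "Chl c1+c2", "Fuco", "Viola"), 4),
               mean = c(750, 130, 200, 22, 750, 130, 200, 22,
                        820, 130, 245, 25, 860, 130, 245, 25)),
    data.frame(species = "L. digitata",
               tissue = rep(rep(c("new", "old"), each = 4), 2),
               season = rep(c("January", "October"), each = 8),
               pigment = rep(c("Chl a", "Chl c1+c2", "Fuco", "Viola"), 4),
               mean = c(175, 30, 60, 5, 300, 50, 85, 12.5,
                        160, 30, 60, 5, 275, 50, 95, 12.5)),
    data.frame(species = "S. latissima",
               tissue = rep(rep(c("new", "old"), each = 4), 2),
               season = rep(c("January", "October"), each = 8),
               pigment = rep(c("Chl a", "Chl c1+c2", "Fuco", "Viola"), 4),
               mean = c(130, 45, 30, 5, 300, 23, 75, 5,
                        340, 60, 100, 10, 162, 30, 60, 5))
  )
}

#' Synthetic pigment concentration table
#'
#' Replicated pigment concentrations (ug pigment per g wet weight) for five
#' macroalgal species across tissue age (new/old) and season
#' (January/October), n replicates per cell, with multiplicative lognormal
#' noise around the configured cell means. The lognormal is parameterised so
#' the arithmetic mean of each cell equals its configured mean.
#'
#' @param seed Integer seed.
#' @param n_rep Replicates per cell (default 3, the sampling design).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.15); `cv = 0` returns the configured means exactly.
#' @return A long-format data.frame with columns `species`, `tissue`,
#'   `season`, `pigment`, `replicate`, `concentration`.
#' @export
make_pigment_table <- function(seed = NULL, n_rep = 3L, cv = 0.15) {
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  means <- pigment_means()
  out <- means[rep(seq_len(nrow(means)), each = n_rep), ]
  out$replicate <- rep(seq_len(n_rep), times = nrow(means))
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    fac <- with_seed(seed,
                     exp(stats::rnorm(nrow(out), mean = -sdlog^2 / 2,
                                      sd = sdlog)))
    out$concentration <- out$mean * fac
  } else {
    out$concentration <- out$mean
  }
  out$mean <- NULL
  rownames(out) <- NULL
  out
}
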