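# absorbance decomposition and peak detection

test_that("baseline_zero shifts to zero at the reference and is idempotent", {
  wl <- 400:800
  flat <- spectrum(wl, rep(0.2, length(wl)), "absorbance")
  expect_true(all(baseline_zero(flat)$values == 0))
  s <- spectrum(wl, gauss(wl, 676, 24) + 0.05, "absorbance")
  z <- baseline_zero(s)
  expect_equal(spec_value_at(z, 800), 0)
  expect_equal(z$values, s$values - spec_value_at(s, 800))
  expect_equal(baseline_zero(z)$values, z$values) # idempotent
  expect_error(baseline_zero(s, ref = 900), "outside grid")
})

test_that("scale_to_pe_peaks recovers a known dilution", {
  fx <- default_fixture(dilution = 0.5)
  tot0 <- baseline_zero(fx$total)
  ext0 <- baseline_zero(fx$extract)
  sc <- scale_to_pe_peaks(tot0, ext0)
  # proportional-at-495 spectra up to the small PS I Soret tail
  expect_equal(sc$scale_factor, 1 / fx$truth$dilution, tolerance = 5e-3)
  # exactly proportional spectra: factor exact, mismatch zero
  half <- tot0
  half$values <- tot0$values * 0.5
  sc2 <- scale_to_pe_peaks(tot0, half)
  expect_equal(sc2$scale_factor, 2)
  expect_equal(sc2$pe_mismatch_545, 0)
  expect_equal(sc2$scaled$values, tot0$values)
  # scale invariance of the output in the extract's own scaling
  sc3 <- scale_to_pe_peaks(tot0, {
    e <- ext0
    e$values <- e$values * 7
    e
  })
  expect_equal(sc3$scaled$values, sc$scaled$values, tolerance = 1e-12)
  # zero at the anchor is an error
  zero <- spectrum(tot0$wavelengths, rep(0, length(tot0$wavelengths)),
                   "absorbance")
  expect_error(scale_to_pe_peaks(tot0, zero), "495")
})

test_that("dilution sweep: scale factor equals 1/d across magnitudes", {
  for (d in c(0.1, 1, 10)) {
    fx <- default_fixture(dilution = d)
    sc <- scale_to_pe_peaks(baseline_zero(fx$total),
                            baseline_zero(fx$extract))
    expect_equal(sc$scale_factor, 1 / d, tolerance = 5e-3)
  }
})

test_that("psi_difference is exact pointwise subtraction, lobes retained", {
  fx <- default_fixture()
  tot0 <- baseline_zero(fx$total)
  d0 <- psi_difference(tot0, tot0)
  expect_true(all(d0$values == 0))
  sc <- scale_to_pe_peaks(tot0, baseline_zero(fx$extract))
  diff <- psi_difference(tot0, sc$scaled)
  # additivity reconstructs the total exactly
  expect_equal(diff$values + sc$scaled$values, tot0$values)
  # red peak of the difference is the PS I band centre
  expect_equal(as.numeric(find_red_peak(diff)), fx$truth$red_center_psi,
               tolerance = 0.1)
  expect_true(is.numeric(attr(diff, "min_excursion")))
  other <- spectrum(400:799, rep(0, 400), "absorbance")
  expect_error(psi_difference(tot0, other), "common")
})

test_that("find_red_peak locates symmetric and mixture peaks", {
  wl <- 400:800
  single <- spectrum(wl, gauss(wl, 676, 24), "absorbance")
  expect_equal(as.numeric(find_red_peak(single)), 676, tolerance = 0.1)
  fx <- default_fixture()
  # oracle: brute-force argmax of the analytic two-Gaussian sum
  oracle <- brute_peak(function(x) 0.4 * gauss(x, 676, 24) +
                         0.6 * gauss(x, 681, 24), 660, 700)
  pk <- as.numeric(find_red_peak(baseline_zero(fx$total)))
  expect_lt(abs(pk - oracle), 0.1)
  expect_lt(abs(pk - 679), 0.5)
  flat <- spectrum(wl, rep(1, length(wl)), "absorbance")
  expect_error(find_red_peak(flat), "no peak")
  mono <- spectrum(wl, wl / 800, "absorbance")
  expect_error(find_red_peak(mono), "no peak")
  expect_error(find_red_peak(single, window = c(700, 640)), "invalid window")
})

test_that("peak detector matches a 0.01-nm oversampled argmax", {
  wl <- 400:800
  for (fwhm in c(10, 24, 50)) {
    for (center in c(655.0, 676.3, 681.7)) {
      s <- spectrum(wl, gauss(wl, center, fwhm), "absorbance")
      oracle <- brute_peak(function(x) gauss(x, center, fwhm), 640, 700)
      expect_lt(abs(as.numeric(find_red_peak(s)) - oracle), 0.1)
    }
  }
})

test_that("find_reflectance_dip mirrors the peak detector", {
  wl <- 400:800
  r <- spectrum(wl, 1 - 0.5 * gauss(wl, 664, 30), "reflectance")
  expect_equal(find_reflectance_dip(r), 664, tolerance = 0.1)
  # dip off-grid: sub-nm refinement
  r2 <- spectrum(wl, 1 - 0.5 * gauss(wl, 651.4, 30), "reflectance")
  expect_equal(find_reflectance_dip(r2), 651.4, tolerance = 0.1)
  mono <- spectrum(wl, wl / 1000, "reflectance")
  expect_error(find_reflectance_dip(mono), "no dip")
  abs_s <- spectrum(wl, 1 - gauss(wl, 664, 30), "absorbance")
  expect_error(find_reflectance_dip(abs_s), "reflectance")
})

test_that("psii_fraction_at_red recovers generator truth across the sweep", {
  for (w in seq(0.2, 0.8, by = 0.1)) {
    for (d in c(0.1, 1, 10)) {
      fx <- make_palmaria_spectra(species_profile(psii_red_fraction = w),
                                  dilution = d)
      dec <- decompose_absorbance(fx$total, fx$extract)
      expect_lt(abs(dec$psii_fraction - w), 0.02)
    }
  }
  # degenerate: component equal to total gives fraction 1
  fx <- default_fixture()
  tot0 <- baseline_zero(fx$total)
  fr <- psii_fraction_at_red(tot0, tot0)
  expect_equal(as.numeric(fr), 1)
  expect_false(attr(fr, "flagged"))
})

test_that("spectral_shift is a signed difference", {
  expect_equal(spectral_shift(681, 676), 5)
  expect_equal(spectral_shift(679, 676), 3)
  expect_equal(spectral_shift(676, 679), -3)
  expect_equal(spectral_shift(680.2, 680.2), 0)
})

test_that("decompose_absorbance bundles a consistent result", {
  fx <- default_fixture()
  dec <- decompose_absorbance(fx$total, fx$extract)
  expect_s3_class(dec, "decomposition_result")
  # conservation: scaled PS II + PS I difference = baseline-corrected total
  tot0 <- baseline_zero(fx$total)
  expect_equal(dec$apsii_scaled$values + dec$psi_diff$values, tot0$values)
  expect_true(dec$peak_total >= 640 && dec$peak_total <= 700)
  expect_equal(dec$shift_psi_psii, dec$peak_psi - dec$peak_psii)
  expect_equal(dec$shift_total_psii, dec$peak_total - dec$peak_psii)
  expect_lt(dec$pe_mismatch_545, 0.05)
})

test_that("smoothing preserves a clean band and reduces noise", {
  wl <- 400:800
  clean <- gauss(wl, 676, 24)
  set.seed(5)
  noisy <- spectrum(wl, clean + rnorm(length(wl), sd = 0.02), "absorbance")
  sm <- smooth_spectrum(noisy)
  expect_lt(mean((sm$values - clean)^2), mean((noisy$values - clean)^2))
  s <- spectrum(wl, clean, "absorbance")
  expect_equal(smooth_spectrum(s)$values[10:390], clean[10:390],
               tolerance = 1e-3)
  expect_error(smooth_spectrum(s, window = 4), "odd")
})
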