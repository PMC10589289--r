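# synthetic-data generator

test_that("gaussian_band matches its definition and closed-form integral", {
  b <- band(676, fwhm = 24, amplitude = 1)
  s <- gaussian_band(b, 400:800)
  expect_equal(spec_value_at(s, 676), 1.0)
  expect_equal(spec_value_at(s, 688), 0.5, tolerance = 1e-12) # center+fwhm/2
  expect_equal(spec_value_at(s, 664), 0.5, tolerance = 1e-12) # symmetric
  # trapezoid quadrature vs amplitude * fwhm * sqrt(pi / (4 log 2))
  wl <- s$wavelengths
  integ <- sum(diff(wl) * (head(s$values, -1) + tail(s$values, -1)) / 2)
  expect_equal(integ, 1 * 24 * sqrt(pi / (4 * log(2))), tolerance = 1e-6)
  expect_equal(integ, 1 * 24 * 1.0645, tolerance = 1e-4)
  expect_error(gaussian_band(band(950, 24, 1), 400:800), "outside grid")
  expect_error(band(676, fwhm = -1, amplitude = 1), "fwhm")
  expect_error(band(676, fwhm = 24, amplitude = -0.1), "amplitude")
})

test_that("make_palmaria_spectra is additive with a faithful truth record", {
  fx <- default_fixture()
  expect_equal(fx$total$values,
               fx$apsii_true$values + fx$psi_true$values + fx$truth$baseline)
  expect_equal(fx$truth$psii_red_fraction, 0.40)
  expect_equal(fx$truth$red_center_psii, 676)
  expect_equal(fx$truth$red_center_psi, 681)
  # extract is the PS II component (plus baseline) times the dilution
  expect_equal(fx$extract$values,
               (fx$apsii_true$values + fx$truth$baseline) *
                 fx$truth$dilution)
  # degenerate: all red absorbance in PS II
  fx1 <- make_palmaria_spectra(species_profile(psii_red_fraction = 1),
                               baseline = 0)
  red <- fx1$total$wavelengths >= 640 & fx1$total$wavelengths <= 700
  expect_equal(fx1$total$values[red], fx1$apsii_true$values[red],
               tolerance = 1e-6)
  expect_error(
    make_palmaria_spectra(structure(list(psii_bands = list(),
                                         psi_bands = list(),
                                         psii_red_fraction = 0.4),
                                    class = "species_profile")),
    "non-empty")
})

test_that("mixture red peak sits at the amplitude-weighted band mean", {
  # emergent-peak property: detected peak of the two-Gaussian sum is within
  # 0.5 nm of 676 w + 681 (1 - w) for w in [0.2, 0.8]
  for (w in seq(0.2, 0.8, by = 0.1)) {
    fx <- make_palmaria_spectra(species_profile(psii_red_fraction = w),
                                baseline = 0)
    pk <- as.numeric(find_red_peak(fx$total))
    expect_lt(abs(pk - (676 * w + 681 * (1 - w))), 0.5)
  }
})

test_that("make_emission_spectrum builds the stated two-band shape", {
  s <- make_emission_spectrum("green", peak685 = 750)
  expect_equal(s$kind, "emission")
  expect_equal(s$meta$excitation_nm, 525)
  expect_equal(s$meta$excitation_ru, 600)
  i <- which.max(s$values)
  expect_equal(s$wavelengths[i], 685)
  # grid maximum = 685-band amplitude plus the analytic shoulder tail there
  expect_equal(max(s$values), 750 * (1 + 0.4 * gauss(685, 730, 50)),
               tolerance = 1e-6)
  b <- make_emission_spectrum("blue", peak685 = 75)
  expect_equal(b$meta$excitation_nm, 452)
  expect_equal(b$meta$excitation_ru, 200)
  # zero peak -> all-zero spectrum
  expect_true(all(make_emission_spectrum("green", 0)$values == 0))
  # no shoulder: value at 730 is just the tail of the 685-nm band
  s0 <- make_emission_spectrum("green", peak685 = 750, shoulder_ratio = 0)
  expect_equal(spec_value_at(s0, 730), gauss(730, 685, 25, 750),
               tolerance = 1e-12)
  expect_error(make_emission_spectrum("green", 750, noise_sd = -1),
               "noise_sd")
})

test_that("simulate_rlc honours the dark step and Webb consistency", {
  rec <- noiseless_rlc()
  expect_equal(rec$dark$F0, 150)
  expect_equal(rec$dark$Fm, 500)
  expect_equal(nrow(rec$steps), 12) # the 12 positive irradiances
  st <- rlc_step_table(rec)
  expect_true(all(diff(st$rETR) >= -1e-12)) # Webb is monotone
  # derived rETR equals the Webb curve exactly (noiseless)
  expect_equal(st$rETR, 0.3 * 50 * (1 - exp(-st$E / 50)), tolerance = 1e-12)
  # an alpha implying phi' > 1 is rejected
  expect_error(simulate_rlc(rlc_sim_config(alpha = 1.2, E_K = 50)),
               "phi")
  expect_error(rlc_sim_config(alpha = -1), "alpha")
  expect_error(rlc_sim_config(irradiances = c(0, 10, 10)), "increasing")
  expect_error(rlc_sim_config(F0_dark = 600, Fm_dark = 500), "F0_dark")
})

test_that("generators are seed-deterministic and leave the RNG alone", {
  a <- simulate_rlc(rlc_sim_config(noise_sd = 5, seed = 42))
  b <- simulate_rlc(rlc_sim_config(noise_sd = 5, seed = 42))
  expect_identical(a, b)
  e1 <- make_emission_spectrum("green", 750, noise_sd = 3, seed = 7)
  e2 <- make_emission_spectrum("green", 750, noise_sd = 3, seed = 7)
  expect_identical(e1, e2)
  p1 <- make_pigment_table(seed = 9)
  p2 <- make_pigment_table(seed = 9)
  expect_identical(p1, p2)
  # caller's RNG stream is restored
  set.seed(1)
  before <- .Random.seed
  invisible(make_pigment_table(seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("pigment table has the configured design and means", {
  pt <- make_pigment_table(seed = 1)
  counts <- table(pt$species, pt$tissue, pt$season, pt$pigment)
  expect_true(all(counts[counts > 0] == 3)) # 3 replicates per present cell
  expect_true(all(pt$concentration >= 0))
  # cv = 0 returns the configured means exactly
  pt0 <- make_pigment_table(cv = 0)
  ulva_chla <- pt0[pt0$species == "Ulva sp." & pt0$pigment == "Chl a", ]
  expect_equal(unique(ulva_chla$concentration[ulva_chla$season == "January"]),
               2500)
  expect_equal(unique(ulva_chla$concentration[ulva_chla$season == "October"]),
               1000)
  # Jan/Oct ratio of generator means is 2.5; noisy cell means converge to it
  set.seed(123)
  means <- replicate(50, {
    p <- make_pigment_table(seed = sample.int(1e6, 1))
    x <- p[p$species == "Ulva sp." & p$pigment == "Chl a", ]
    c(jan = mean(x$concentration[x$season == "January"]),
      oct = mean(x$concentration[x$season == "October"]))
  })
  expect_equal(mean(means["jan", ]) / mean(means["oct", ]), 2.5,
               tolerance = 0.05)
})
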