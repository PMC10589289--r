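# Shared fixtures, all built in code.

# Default red-algal absorbance fixture: PS II red band at 676 nm (weight
# 0.40), PS I at 681 nm (weight 0.60), fwhm 24 nm.
default_fixture <- function(...) make_palmaria_spectra(...)

# Noiseless RLC at the 13-step protocol.
noiseless_rlc <- function(alpha = 0.30, E_K = 50) {
  simulate_rlc(rlc_sim_config(alpha = alpha, E_K = E_K, noise_sd = 0))
}

# Analytic Gaussian for oracle computations.
gauss <- function(x, center, fwhm, amp = 1) {
  amp * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

# Brute-force argmax of a function on a fine grid: independent oracle for
# the quadratic-refined peak detector.
brute_peak <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  x[which.max(f(x))]
}
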