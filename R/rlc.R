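#' Dark-acclimated fluorescence reading
#'
#' Minimum (`F0`) and maximum (`Fm`) chlorophyll fluorescence after dark
#' acclimation, in mV, measured with all PS II reaction centres open.
#'
#' @param F0 Minimum fluorescence, mV; `0 <= F0 <= Fm`.
#' @param Fm Maximum fluorescence, mV; `> 0`.
#' @return A `dark_reading` object.
#' @export
dark_reading <- function(F0, Fm) {
  if (!is.finite(Fm) || Fm <= 0) stop("Fm must be > 0", call. = FALSE)
  if (!is.finite(F0) || F0 < 0) stop("F0 must be >= 0", call. = FALSE)
  if (F0 > Fm) stop("inverted dark reading: F0 > Fm", call. = FALSE)
  structure(list(F0 = F0, Fm = Fm), class = "dark_reading")
}

#' Rapid light curve record
#'
#' One sample's RLC: the dark reading plus an ordered table of light steps.
#' Steps are sorted by ascending actinic irradiance `E`; a first step with
#' `E = 0` is permitted and treated as the dark reading.
#'
#' @param dark A [dark_reading()].
#' @param steps data.frame with columns `E` (umol photons m^-2 s^-1), `F` and
#'   `Fm_prime` (mV). `Fm_prime` must be positive.
#' @param meta Named list: sample id, species, tissue age, season,
#'   temperature.
#' @return An `rlc_record` object.
#' @export
rlc_record <- function(dark, steps, meta = list()) {
  stopifnot(inherits(dark, "dark_reading"), is.data.frame(steps))
  need <- c("E", "F", "Fm_prime")
  if (!all(need %in% names(steps))) {
    stop("steps must have columns E, F, Fm_prime", call. = FALSE)
  }
  steps <- steps[order(steps$E), need, drop = FALSE]
  rownames(steps) <- NULL
  if (any(steps$E < 0)) stop("irradiances must be >= 0", call. = FALSE)
  if (any(duplicated(steps$E))) {
    stop("duplicate irradiance steps", call. = FALSE)
  }
  if (any(steps$Fm_prime <= 0)) {
    stop("Fm_prime must be positive at every step", call. = FALSE)
  }
  structure(list(dark = dark, steps = steps, meta = meta),
            class = "rlc_record")
}

#' @export
print.rlc_record <- function(x, ...) {
  cat(sprintf("<rlc_record: %d light steps, F0=%g, Fm=%g mV>\n",
              sum(x$steps$E > 0), x$dark$F0, x$dark$Fm))
  invisible(x)
}

#' Maximum quantum yield of PS II, Fv/Fm
#'
#' `(Fm - F0) / Fm` from the dark-acclimated reading; the standard index of
#' maximal PS II photochemical efficiency (~ 0.6-0.8 in healthy tissue).
#'
#' @param dark A [dark_reading()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' max_quantum_yield(dark_reading(150, 600)) # 0.75
#' @export
max_quantum_yield <- function(dark) {
  stopifnot(inherits(dark, "dark_reading"))
  (dark$Fm - dark$F0) / dark$Fm
}

#' Operational PS II quantum yield in actinic light
#'
#' `(F'_m - F) / F'_m` for one light step. Negative values, which arise from
#' instrument noise when `F` slightly exceeds `F'_m`, are clipped to zero and
#' flagged via the `"clipped"` attribute rather than propagated into the fit.
#'
#' @param F Minimum fluorescence in actinic light, mV.
#' @param Fm_prime Maximum fluorescence in actinic light, mV; `> 0`.
#' @return Fraction in `[0, 1]` with attribute `clipped` (logical).
#' @export
operational_yield <- function(F, Fm_prime) {
  if (any(!is.finite(Fm_prime)) || any(Fm_prime <= 0)) {
    stop("Fm_prime must be > 0", call. = FALSE)
  }
  phi <- (Fm_prime - F) / Fm_prime
  clipped <- phi < 0
  phi[clipped] <- 0
  attr(phi, "clipped") <- clipped
  phi
}

#' Relative electron transport rate
#'
#' `rETR = phi' * E_PAR`. Relative because no absorptance factor or PS II
#' absorption fraction is applied.
#'
#' @param phi_prime Operational yield, in `[0, 1]`.
#' @param E Actinic irradiance, umol photons m^-2 s^-1; `>= 0`.
#' @return rETR (dimensionless).
#' @export
relative_etr <- function(phi_prime, E) {
  if (any(phi_prime < 0 | phi_prime > 1)) {
    stop("phi_prime must be in [0, 1]", call. = FALSE)
  }
  if (any(E < 0)) stop("E must be >= 0", call. = FALSE)
  phi_prime * E
}

#' Per-step yield and rETR table for an RLC record
#'
#' @param record An [rlc_record()].
#' @return data.frame with columns `E`, `phi_prime`, `rETR`, `clipped`.
#' @export
rlc_step_table <- function(record) {
  stopifnot(inherits(record, "rlc_record"))
  st <- record$steps
  phi <- operational_yield(st$F, st$Fm_prime)
  data.frame(E = st$E,
             phi_prime = as.numeric(phi),
             rETR = relative_etr(as.numeric(phi), st$E),
             clipped = attr(phi, "clipped"))
}

# Webb (1974) saturating exponential.
webb_retr <- function(E, alpha, E_K) alpha * E_K * (1 - exp(-E / E_K))

#' Fit the Webb photosynthesis-irradiance model to an rETR curve
#'
#' Minimises `sum((rETR_obs - alpha * E_K * (1 - exp(-E/E_K)))^2)` over
#' `(alpha, E_K)` by Nelder-Mead on the log-parameters, which enforces
#' positivity without hard constraints. The model passes through the origin
#' exactly, so the `E = 0` point carries no information and is excluded.
#' Starting values: `alpha` from the slope through the origin of the two
#' lowest-irradiance points; `E_K` as the smallest `E` where rETR reaches
#' 63% of its observed maximum (the Webb model reaches `(1 - 1/e) ~ 0.632` of
#' its asymptote at `E = E_K`), falling back to `median(E)`.
#'
#' @param E Irradiances, umol photons m^-2 s^-1.
#' @param rETR Observed relative electron transport rates.
#' @param Fv_Fm Optional dark-acclimated maximum quantum yield to carry in
#'   the result (not used by the fit).
#' @param maxit Nelder-Mead iteration budget (default 2000).
#' @return A `photo_params` object: `alpha`, `rETR_max`, `E_K`, `Fv_Fm`,
#'   `sse`, `converged`, `n_points`.
#' @examples
#' E <- c(7, 14, 20, 27, 38, 56, 85, 125, 186, 243, 341, 445)
#' fit_webb(E, 0.3 * 50 * (1 - exp(-E / 50)))
#' @export
fit_webb <- function(E, rETR, Fv_Fm = NA_real_, maxit = 2000L) {
  keep <- E > 0
  E <- E[keep]
  rETR <- rETR[keep]
  if (length(E) < 4L) {
    stop("need at least 4 points with E > 0", call. = FALSE)
  }
  if (all(rETR == 0)) stop("no photosynthetic signal", call. = FALSE)
  ord <- order(E)
  E <- E[ord]
  rETR <- rETR[ord]

  alpha0 <- mean(rETR[1:2] / E[1:2])
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- max(rETR) / stats::median(E)
  sat <- E[rETR >= 0.63 * max(rETR)]
  ek0 <- if (length(sat)) min(sat) else stats::median(E)
  if (!is.finite(ek0) || ek0 <= 0) ek0 <- stats::median(E)

  sse <- function(p) {
    r <- rETR - webb_retr(E, exp(p[1]), exp(p[2]))
    sum(r * r)
  }
  opt <- stats::optim(log(c(alpha0, ek0)), sse, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  alpha <- exp(opt$par[1])
  E_K <- exp(opt$par[2])
  structure(
    list(alpha = alpha,
         rETR_max = alpha * E_K,
         E_K = E_K,
         Fv_Fm = Fv_Fm,
         sse = opt$value,
         converged = opt$convergence == 0L,
         n_points = length(E)),
    class = "photo_params"
  )
}

#' @export
print.photo_params <- function(x, ...) {
  cat(sprintf(
    "<photo_params: alpha=%.4g, rETR_max=%.4g, E_K=%.4g, Fv/Fm=%s, sse=%.3g%s>\n",
    x$alpha, x$rETR_max, x$E_K,
    ifelse(is.na(x$Fv_Fm), "NA", sprintf("%.3f", x$Fv_Fm)),
    x$sse, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Light saturation parameter
#'
#' `E_K = rETR_max / alpha`: the irradiance where the initial slope meets the
#' photosynthetic maximum; the Webb curve reaches 63% of its asymptote there.
#'
#' @param rETR_max Maximum relative electron transport rate.
#' @param alpha Photosynthetic efficiency (initial slope); `> 0`.
#' @return E_K in umol photons m^-2 s^-1.
#' @examples
#' light_saturation(15, 0.30) # 50
#' @export
light_saturation <- function(rETR_max, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("alpha must be > 0", call. = FALSE)
  }
  rETR_max / alpha
}

#' Signal-quality check on fluorescence readings
#'
#' The measuring protocol requires fluorescence between 200 and 600 mV
#' (inclusive) for an adequate signal-to-noise ratio. Readings outside the
#' window are flagged; a QC failure never aborts processing.
#'
#' @param record An [rlc_record()].
#' @param bounds Inclusive window in mV (default `c(200, 600)`).
#' @return A list with `pass` (logical) and `flags`, a data.frame of
#'   offending readings (`where`, `quantity`, `value`).
#' @export
qc_fluorescence <- function(record, bounds = c(200, 600)) {
  stopifnot(inherits(record, "rlc_record"))
  out_of <- function(v) v < bounds[1] | v > bounds[2]
  flags <- data.frame(where = character(), quantity = character(),
                      value = numeric())
  if (out_of(record$dark$F0)) {
    flags <- rbind(flags, data.frame(where = "dark", quantity = "F0",
                                     value = record$dark$F0))
  }
  if (out_of(record$dark$Fm)) {
    flags <- rbind(flags, data.frame(where = "dark", quantity = "Fm",
                                     value = record$dark$Fm))
  }
  st <- record$steps
  for (q in c("F", "Fm_prime")) {
    bad <- which(out_of(st[[q]]))
    if (length(bad)) {
      flags <- rbind(flags, data.frame(
        where = sprintf("E=%g", st$E[bad]), quantity = q,
        value = st[[q]][bad]))
    }
  }
  rownames(flags) <- NULL
  list(pass = nrow(flags) == 0L, flags = flags, bounds = bounds)
}

#' Fit an RLC record end to end
#'
#' Convenience wrapper: computes Fv/Fm from the dark reading, the per-step
#' yield/rETR table, the QC report, and the Webb fit, in one call.
#'
#' @param record An [rlc_record()].
#' @param ... Passed to [fit_webb()].
#' @return A list with `params` ([fit_webb()] result including `Fv_Fm`),
#'   `steps` (the [rlc_step_table()]) and `qc` ([qc_fluorescence()] report).
#' @export
fit_rlc <- function(record, ...) {
  stopifnot(inherits(record, "rlc_record"))
  steps <- rlc_step_table(record)
  fvfm <- max_quantum_yield(record$dark)
  params <- fit_webb(steps$E, steps$rETR, Fv_Fm = fvfm, ...)
  list(params = params, steps = steps, qc = qc_fluorescence(record))
}
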