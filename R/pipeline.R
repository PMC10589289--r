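#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end analysis uses. All
#' randomness in a pipeline run flows from `seed`, so two runs with equal
#' configurations produce bit-identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed (default 1).
#' @param simulate Generate the synthetic input bundle before analysing
#'   (default `TRUE`; set `FALSE` to analyse files already in `input_dir`).
#' @param input_dir Directory holding input files when `simulate = FALSE`
#'   (defaults to `out_dir`).
#' @param red_window Red-peak search window, nm.
#' @param dip_window Reflectance-dip window, nm.
#' @param pe_anchors PE normalization anchors, nm.
#' @param qc_bounds Fluorescence QC window, mV.
#' @param rlc_noise_sd Fluorescence noise sd (mV) for simulated RLCs.
#' @param n_rlc Number of simulated RLC samples (default 6).
#' @param verbose Log progress to stderr (default `TRUE`).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir = tempfile("phycopam_run_"),
                            seed = 1L,
                            simulate = TRUE,
                            input_dir = NULL,
                            red_window = c(640, 700),
                            dip_window = c(600, 700),
                            pe_anchors = c(495, 545),
                            qc_bounds = c(200, 600),
                            rlc_noise_sd = 2,
                            n_rlc = 6L,
                            verbose = TRUE) {
  for (w in list(red_window, dip_window, pe_anchors, qc_bounds)) {
    if (length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2]) {
      stop("windows/anchors/bounds must be increasing pairs", call. = FALSE)
    }
  }
  if (red_window[1] < 400 || red_window[2] > 800 ||
      dip_window[1] < 400 || dip_window[2] > 800) {
    stop("spectral windows must lie within 400-800 nm", call. = FALSE)
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    stop("seed must be an integer", call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate,
                 input_dir = input_dir %||% out_dir,
                 red_window = red_window, dip_window = dip_window,
                 pe_anchors = pe_anchors, qc_bounds = qc_bounds,
                 rlc_noise_sd = rlc_noise_sd, n_rlc = as.integer(n_rlc),
                 verbose = verbose),
            class = "pipeline_config")
}

config_hash <- function(config) {
  fields <- config[setdiff(names(config),
                           c("verbose", "out_dir", "input_dir"))]
  fnv1a_hash(paste(deparse(fields), collapse = ""))
}

plog <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[phycopam] ", sprintf(...))
}

write_result_kv <- function(path, x, config) {
  lines <- c(
    sprintf("# phycopam_version: %s",
            as.character(utils::packageVersion("phycopam"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("%s: %s", names(x),
            vapply(x, function(v) paste(format(v, digits = 15),
                                        collapse = " "), ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) optionally simulate the synthetic input bundle (RLC tables,
#' the red-algal absorbance pair, blue/green emission spectra, the pigment
#' table) into the output directory; (2) fit the Webb model to every RLC
#' file; (3) decompose the absorbance pair; (4) summarise the emission pair
#' and compute raw and excitation-adjusted green:blue ratios; (5) run the
#' season / tissue-age ANOVAs on fitted E_K, Fv/Fm and on the pigment
#' table. A failing sample is logged and skipped; the remaining samples
#' continue, and the bundle records the failures.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list): `rlc_fits`, `decomposition`, `emission`,
#'   `anova`, `failures`, `config_hash`, `out_dir`. Summary files are
#'   written under `config$out_dir`, each stamped with the package version
#'   and configuration hash.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- character()
  hash <- config_hash(config)
  plog(config, "run starting (config hash %s)", hash)

  if (config$simulate) {
    plog(config, "simulating input bundle (seed %d)", config$seed)
    seasons <- rep(c("January", "October"), length.out = config$n_rlc)
    for (i in seq_len(config$n_rlc)) {
      # seasonal contrast in E_K mirrors the new-tissue-in-winter pattern
      ek <- if (seasons[i] == "January") 100 else 50
      cfg <- rlc_sim_config(alpha = 0.30, E_K = ek,
                            noise_sd = config$rlc_noise_sd,
                            seed = config$seed * 1000L + i)
      rec <- simulate_rlc(cfg)
      rec$meta <- c(rec$meta, list(sample = sprintf("rlc%02d", i),
                                   season = seasons[i],
                                   tissue = c("new", "old")[
                                     1 + ((i - 1L) %/% 2L) %% 2L]))
      write_rlc(rec, file.path(config$out_dir,
                               sprintf("rlc%02d.csv", i)))
    }
    fx <- make_palmaria_spectra()
    write_spectrum(fx$total, file.path(config$out_dir, "absorbance_total.csv"))
    write_spectrum(fx$extract,
                   file.path(config$out_dir, "absorbance_extract.csv"))
    writeLines(c("# synthetic ground truth",
                 sprintf("%s: %s", names(fx$truth),
                         vapply(fx$truth, format, ""))),
               file.path(config$out_dir, "absorbance_truth.txt"))
    g <- make_emission_spectrum("green", peak685 = 750, noise_sd = 5,
                                seed = config$seed * 1000L + 101L)
    b <- make_emission_spectrum("blue", peak685 = 75, noise_sd = 5,
                                seed = config$seed * 1000L + 102L)
    write_spectrum(g, file.path(config$out_dir, "emission_green.csv"))
    write_spectrum(b, file.path(config$out_dir, "emission_blue.csv"))
    write_pigment_table(make_pigment_table(seed = config$seed * 1000L + 201L),
                        file.path(config$out_dir, "pigments.csv"))
  }

  in_dir <- if (config$simulate) config$out_dir else config$input_dir

  # --- RLC fits ---
  rlc_files <- sort(list.files(in_dir, pattern = "^rlc[0-9]+\\.csv$",
                               full.names = TRUE))
  fits <- list()
  for (f in rlc_files) {
    res <- tryCatch({
      rec <- read_rlc(f)
      fit <- fit_rlc(rec)
      fit$meta <- rec$meta
      fit
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", basename(f),
                                       conditionMessage(e)))
      plog(config, "RLC fit FAILED for %s: %s", basename(f),
           conditionMessage(e))
      NULL
    })
    if (!is.null(res)) fits[[basename(f)]] <- res
  }
  plog(config, "fitted %d/%d RLC files", length(fits), length(rlc_files))
  if (length(fits)) {
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      p <- fits[[nm]]$params
      data.frame(file = nm,
                 season = fits[[nm]]$meta$season %||% NA,
                 tissue = fits[[nm]]$meta$tissue %||% NA,
                 alpha = p$alpha, rETR_max = p$rETR_max, E_K = p$E_K,
                 Fv_Fm = p$Fv_Fm, sse = p$sse, converged = p$converged,
                 qc_pass = fits[[nm]]$qc$pass)
    }))
    utils::write.table(tab, file.path(config$out_dir, "rlc_params.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    tab <- NULL
  }

  # --- absorbance decomposition ---
  decomp <- tryCatch({
    total <- read_spectrum(file.path(in_dir, "absorbance_total.csv"))
    extract <- read_spectrum(file.path(in_dir, "absorbance_extract.csv"))
    d <- decompose_absorbance(total, extract,
                              anchors = config$pe_anchors,
                              window = config$red_window)
    write_result_kv(file.path(config$out_dir, "decomposition.txt"),
                    list(peak_total_nm = d$peak_total,
                         peak_psii_nm = d$peak_psii,
                         peak_psi_nm = d$peak_psi,
                         psii_fraction = d$psii_fraction,
                         shift_psi_psii_nm = d$shift_psi_psii,
                         shift_total_psii_nm = d$shift_total_psii,
                         scale_factor = d$scale_factor,
                         pe_mismatch_545 = d$pe_mismatch_545),
                    config)
    d
  }, error = function(e) {
    failures <<- c(failures, paste("decomposition:", conditionMessage(e)))
    plog(config, "decomposition FAILED: %s", conditionMessage(e))
    NULL
  })

  # --- emission analysis ---
  emis <- tryCatch({
    g <- read_spectrum(file.path(in_dir, "emission_green.csv"))
    b <- read_spectrum(file.path(in_dir, "emission_blue.csv"))
    gs <- summarize_emission(g)
    bs <- summarize_emission(b)
    raw <- green_blue_ratio(gs, bs)
    adj <- adjust_for_excitation(
      raw,
      green_setting = gs$excitation %||% excitation_setting("green"),
      blue_setting = bs$excitation %||% excitation_setting("blue"))
    write_result_kv(file.path(config$out_dir, "emission.txt"),
                    list(green_peak685 = gs$peak685,
                         blue_peak685 = bs$peak685,
                         raw_ratio = raw,
                         adjusted_ratio = as.numeric(adj)),
                    config)
    list(green = gs, blue = bs, raw_ratio = raw,
         adjusted_ratio = as.numeric(adj))
  }, error = function(e) {
    failures <<- c(failures, paste("emission:", conditionMessage(e)))
    plog(config, "emission analysis FAILED: %s", conditionMessage(e))
    NULL
  })

  # --- statistics ---
  stats_res <- tryCatch({
    out <- list()
    if (!is.null(tab) && length(unique(stats::na.omit(tab$season))) >= 2) {
      ok <- !is.na(tab$season) & !is.na(tab$tissue)
      if (length(unique(tab$tissue[ok])) >= 2 &&
          all(table(tab$season[ok], tab$tissue[ok]) > 0)) {
        out$E_K <- factorial_anova(tab$E_K[ok], tab$season[ok],
                                   tab$tissue[ok])
        out$Fv_Fm <- factorial_anova(tab$Fv_Fm[ok], tab$season[ok],
                                     tab$tissue[ok])
      } else {
        out$E_K <- factorial_anova(tab$E_K, tab$season)
        out$Fv_Fm <- factorial_anova(tab$Fv_Fm, tab$season)
      }
    }
    pig_path <- file.path(in_dir, "pigments.csv")
    if (file.exists(pig_path)) {
      pig <- read_pigment_table(pig_path)
      per_species <- split(pig, pig$species)
      out$pigments <- lapply(per_species, function(dd) {
        per_pig <- split(dd, dd$pigment)
        lapply(per_pig, function(pp) {
          if (all(pp$concentration == 0)) return(NULL)
          if (length(unique(pp$tissue)) >= 2) {
            factorial_anova(pp$concentration, pp$season, pp$tissue)
          } else {
            factorial_anova(pp$concentration, pp$season)
          }
        })
      })
    }
    anova_lines <- character()
    flatten <- function(fit, label) {
      if (is.null(fit)) return(character())
      t <- fit$table
      sprintf("%s,%s,%d,%.10g,%.10g,%.10g", label, t$effect, t$df, t$ss,
              ifelse(is.na(t$F), NaN, t$F), ifelse(is.na(t$p), NaN, t$p))
    }
    for (nm in intersect(c("E_K", "Fv_Fm"), names(out))) {
      anova_lines <- c(anova_lines, flatten(out[[nm]], nm))
    }
    if (!is.null(out$pigments)) {
      for (sp in names(out$pigments)) {
        for (pg in names(out$pigments[[sp]])) {
          anova_lines <- c(anova_lines,
                           flatten(out$pigments[[sp]][[pg]],
                                   paste(sp, pg, sep = "|")))
        }
      }
    }
    writeLines(c(sprintf("# phycopam_version: %s",
                         as.character(utils::packageVersion("phycopam"))),
                 sprintf("# config_hash: %s", hash),
                 "analysis,effect,df,ss,F,p", anova_lines),
               file.path(config$out_dir, "anova.csv"))
    out
  }, error = function(e) {
    failures <<- c(failures, paste("stats:", conditionMessage(e)))
    plog(config, "statistics FAILED: %s", conditionMessage(e))
    NULL
  })

  plog(config, "run finished with %d failure(s)", length(failures))
  structure(list(rlc_fits = fits, rlc_table = tab,
                 decomposition = decomp, emission = emis,
                 anova = stats_res, failures = failures,
                 config_hash = hash, out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d RLC fits, %d failure(s), hash %s>\n",
              length(x$rlc_fits), length(x$failures), x$config_hash))
  invisible(x)
}
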