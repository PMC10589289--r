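# Delimited-text formats. Spectra are two columns (wavelength_nm, value)
# preceded by `# key: value` metadata headers; RLC tables have columns
# step, E_PAR, F, Fm_prime; pigment tables are long-format. Comma is the
# default delimiter, tab is accepted.

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (!grepl(":", body)) next
    key <- trimws(sub(":.*$", "", body))
    val <- trimws(sub("^[^:]*:", "", body))
    meta[[key]] <- val
  }
  meta
}

#' Read a spectrum from delimited text
#'
#' Format: optional `# key: value` metadata header lines, then a header row
#' `wavelength_nm,value` (or tab-separated) and one row per grid point. The
#' `kind` metadata key is required; emission spectra additionally require
#' `excitation_nm` and `excitation_ru`. Unknown metadata keys are preserved.
#'
#' @param path File path.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) {
    stop("no data rows in spectrum file: ", path, call. = FALSE)
  }
  if (is.null(meta$kind)) {
    stop("spectrum file missing required metadata key 'kind': ", path,
         call. = FALSE)
  }
  if (identical(meta$kind, "emission")) {
    for (key in c("excitation_nm", "excitation_ru")) {
      if (is.null(meta[[key]])) {
        stop(sprintf("emission spectrum file missing metadata key '%s': %s",
                     key, path), call. = FALSE)
      }
    }
  }
  sep <- detect_sep(body[1])
  header <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  if (length(header) != 2L) {
    stop("spectrum files must have exactly two columns: ", path,
         call. = FALSE)
  }
  rows <- strsplit(body[-1], sep, fixed = TRUE)
  bad <- which(lengths(rows) != 2L)
  if (length(bad)) {
    stop(sprintf("ragged row at data line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  }
  wl <- as.numeric(vapply(rows, `[[`, "", 1L))
  v <- as.numeric(vapply(rows, `[[`, "", 2L))
  if (anyNA(wl) || anyNA(v)) {
    bad <- which(is.na(wl) | is.na(v))[1]
    stop(sprintf("non-numeric value at data line %d of %s", bad + 1L, path),
         call. = FALSE)
  }
  nonmono <- which(diff(wl) <= 0)
  if (length(nonmono)) {
    stop(sprintf("non-increasing wavelength at data line %d of %s",
                 nonmono[1] + 2L, path), call. = FALSE)
  }
  spectrum(wl, v, kind = meta$kind,
           meta = meta[setdiff(names(meta), "kind")])
}

#' Write a spectrum to delimited text
#'
#' Inverse of [read_spectrum()]: `read_spectrum(write_spectrum(s, f))`
#' reproduces grid and values exactly (values are written with full
#' precision).
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",") {
  stopifnot(is_spectrum(s))
  meta <- c(list(kind = s$kind), s$meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(x) as.character(x)[1], ""))
  rows <- paste(format(s$wavelengths, digits = 17, trim = TRUE,
                       scientific = FALSE),
                format(s$values, digits = 17, trim = TRUE),
                sep = sep)
  writeLines(c(hdr, paste("wavelength_nm", "value", sep = sep), rows), path)
  invisible(path)
}

#' Read a rapid-light-curve table
#'
#' Columns `step`, `E_PAR`, `F`, `Fm_prime` (comma- or tab-separated,
#' optional `#` metadata header lines). The row with `E_PAR = 0` is the dark
#' reading (`F0`, `Fm`); exactly one such row is required. Rows may appear
#' in any order; steps are sorted by irradiance.
#'
#' @param path File path.
#' @return An [rlc_record()].
#' @export
read_rlc <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in RLC file: ", path,
                              call. = FALSE)
  sep <- detect_sep(body[1])
  df <- utils::read.table(text = body, sep = sep, header = TRUE)
  need <- c("step", "E_PAR", "F", "Fm_prime")
  if (!all(need %in% names(df))) {
    stop("RLC file must have columns step, E_PAR, F, Fm_prime: ", path,
         call. = FALSE)
  }
  if (any(duplicated(df$E_PAR))) {
    stop("duplicate E_PAR values in RLC file: ", path, call. = FALSE)
  }
  dark_row <- which(df$E_PAR == 0)
  if (length(dark_row) != 1L) {
    stop("RLC file must contain exactly one E_PAR = 0 (dark) row: ", path,
         call. = FALSE)
  }
  dark <- dark_reading(df$F[dark_row], df$Fm_prime[dark_row])
  light <- df[-dark_row, , drop = FALSE]
  rlc_record(dark,
             data.frame(E = light$E_PAR, F = light$F,
                        Fm_prime = light$Fm_prime),
             meta = meta)
}

#' Write a rapid-light-curve table
#'
#' @param record An [rlc_record()].
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_rlc <- function(record, path, sep = ",") {
  stopifnot(inherits(record, "rlc_record"))
  hdr <- if (length(record$meta)) {
    sprintf("# %s: %s", names(record$meta),
            vapply(record$meta, function(x) as.character(x)[1], ""))
  } else {
    character()
  }
  df <- rbind(
    data.frame(step = 0L, E_PAR = 0, F = record$dark$F0,
               Fm_prime = record$dark$Fm),
    data.frame(step = seq_len(nrow(record$steps)),
               E_PAR = record$steps$E, F = record$steps$F,
               Fm_prime = record$steps$Fm_prime)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a long-format pigment table
#'
#' Columns `species`, `tissue`, `season`, `pigment`, `replicate`,
#' `concentration` (ug pigment per g wet weight), comma- or tab-separated.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_pigment_table <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, sep = detect_sep(first), header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "tissue", "season", "pigment", "replicate",
            "concentration")
  if (!all(need %in% names(df))) {
    stop("pigment table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$concentration < 0)) {
    stop("negative pigment concentration in ", path, call. = FALSE)
  }
  df
}

#' @rdname read_pigment_table
#' @param df Pigment table data.frame.
#' @param sep Field separator (default `","`).
#' @export
write_pigment_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
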