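# MGF / MSP text readers and writers. Both formats are line-oriented; the
# readers track line numbers so malformed records can be reported precisely.

# Record-level error helper: messages already carry their line number;
# lenient mode downgrades them to a warning and skips the record.
record_error <- function(msg, lenient) {
  if (lenient) {
    warning(msg, call. = FALSE)
    NULL
  } else {
    stop(msg, call. = FALSE)
  }
}

parse_peak_lines <- function(lines, line_numbers) {
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, function(p) length(p) < 2, logical(1))
  if (any(bad)) {
    stop(sprintf("line %d: malformed peak line '%s'",
                 line_numbers[which(bad)[1]], lines[which(bad)[1]]),
         call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  if (anyNA(mz) || anyNA(int)) {
    i <- which(is.na(mz) | is.na(int))[1]
    stop(sprintf("line %d: non-numeric peak line '%s'",
                 line_numbers[i], lines[i]), call. = FALSE)
  }
  list(mz = mz, intensity = int)
}

#' Read a Mascot Generic Format (MGF) spectral library
#'
#' Records are delimited by `BEGIN IONS` / `END IONS`. `PEPMASS` (first token)
#' becomes the precursor m/z, `TITLE` (or a generated ordinal) the identifier;
#' `INCHIKEY` / `INCHIAUX` are captured when present and all other
#' `KEY=VALUE` parameters are stored as opaque metadata. Peaks are sorted and
#' identical m/z values merged by the [spectrum()] constructor.
#'
#' @param path Path to an MGF file.
#' @param lenient When `TRUE`, a malformed record raises a warning carrying
#'   its line number and is skipped; when `FALSE` (default) it is fatal.
#' @return An `ms_library`.
#' @export
read_mgf <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  ordinal <- 0L
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (toupper(ln) != "BEGIN IONS") {
      stop(sprintf("line %d: expected BEGIN IONS, found '%s'", i, ln),
           call. = FALSE)
    }
    start <- i
    i <- i + 1L
    params <- list()
    peak_lines <- character()
    peak_lnos <- integer()
    closed <- FALSE
    while (i <= n) {
      ln <- trimws(lines[i])
      if (toupper(ln) == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (nzchar(ln)) {
        if (grepl("^[A-Za-z]", ln) && grepl("=", ln, fixed = TRUE)) {
          eq <- regexpr("=", ln, fixed = TRUE)
          params[[toupper(substr(ln, 1, eq - 1))]] <-
            substr(ln, eq + 1, nchar(ln))
        } else {
          peak_lines <- c(peak_lines, ln)
          peak_lnos <- c(peak_lnos, i)
        }
      }
      i <- i + 1L
    }
    ordinal <- ordinal + 1L
    rec <- tryCatch({
      if (!closed) stop(sprintf("line %d: record has no END IONS", start),
                        call. = FALSE)
      if (is.null(params$PEPMASS)) {
        stop(sprintf("line %d: record '%s' is missing PEPMASS", start,
                     if (is.null(params$TITLE)) paste0("#", ordinal)
                     else params$TITLE),
             call. = FALSE)
      }
      prec <- suppressWarnings(
        as.numeric(strsplit(trimws(params$PEPMASS), "[ \t]+")[[1]][1]))
      if (is.na(prec)) {
        stop(sprintf("line %d: non-numeric PEPMASS '%s'", start,
                     params$PEPMASS), call. = FALSE)
      }
      pk <- parse_peak_lines(peak_lines, peak_lnos)
      id <- if (!is.null(params$TITLE)) params$TITLE
            else sprintf("spectrum_%d", ordinal)
      key <- params$INCHIKEY
      if (is.null(key)) key <- params$INCHIAUX
      meta <- params[setdiff(names(params),
                             c("PEPMASS", "TITLE", "INCHIKEY"))]
      spectrum(pk$mz, pk$intensity, precursor_mz = prec, id = id,
               inchikey = key, metadata = meta)
    }, error = function(e) record_error(conditionMessage(e), lenient))
    if (!is.null(rec)) spectra[[length(spectra) + 1L]] <- rec
  }
  spectrum_library(spectra, source = path)
}

#' Write a spectral library as MGF
#'
#' Precursor m/z and peaks are written with six decimal places, so a
#' read/write round trip reproduces them to 1e-6. Output is deterministic:
#' writing the same library twice produces byte-identical files.
#'
#' @param x A non-empty `ms_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  stopifnot(inherits(x, "ms_library"))
  if (length(x$spectra) == 0L) {
    stop("refusing to write an empty library", call. = FALSE)
  }
  blocks <- vapply(x$spectra, function(s) {
    hdr <- c("BEGIN IONS",
             paste0("TITLE=", s$id),
             sprintf("PEPMASS=%.6f", s$precursor_mz))
    if (!is.null(s$inchikey)) hdr <- c(hdr, paste0("INCHIKEY=", s$inchikey))
    if (length(s$metadata)) {
      hdr <- c(hdr, paste0(names(s$metadata), "=",
                           vapply(s$metadata, as.character, character(1))))
    }
    paste(c(hdr, sprintf("%.6f %.6f", s$mz, s$intensity), "END IONS"),
          collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read a NIST-style MSP spectral library
#'
#' Records carry `Name:`, `PrecursorMZ:` and `Num Peaks:` headers followed by
#' that many `mz intensity` (or tab-separated) peak lines; records are
#' separated by blank lines. A `Num Peaks` count that disagrees with the
#' number of parsed peak lines is a record-level error.
#'
#' @inheritParams read_mgf
#' @return An `ms_library`.
#' @export
read_msp <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  ordinal <- 0L
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    start <- i
    headers <- list()
    # header block: "Key: value" lines up to and including "Num Peaks:"
    while (i <= n && nzchar(trimws(lines[i])) &&
           grepl("^[A-Za-z][A-Za-z0-9_ /]*:", lines[i])) {
      ln <- trimws(lines[i])
      colon <- regexpr(":", ln, fixed = TRUE)
      key <- toupper(trimws(substr(ln, 1, colon - 1)))
      headers[[key]] <- trimws(substr(ln, colon + 1, nchar(ln)))
      i <- i + 1L
      if (key == "NUM PEAKS") break
    }
    peak_lines <- character()
    peak_lnos <- integer()
    while (i <= n && nzchar(trimws(lines[i]))) {
      peak_lines <- c(peak_lines, trimws(lines[i]))
      peak_lnos <- c(peak_lnos, i)
      i <- i + 1L
    }
    ordinal <- ordinal + 1L
    rec <- tryCatch({
      if (is.null(headers$NAME)) {
        stop(sprintf("line %d: record is missing Name:", start),
             call. = FALSE)
      }
      prec_raw <- headers$PRECURSORMZ
      if (is.null(prec_raw)) prec_raw <- headers$PRECURSOR_MZ
      if (is.null(prec_raw)) {
        stop(sprintf("line %d: record '%s' is missing PrecursorMZ:", start,
                     headers$NAME), call. = FALSE)
      }
      prec <- suppressWarnings(as.numeric(prec_raw))
      if (is.na(prec)) {
        stop(sprintf("line %d: non-numeric PrecursorMZ '%s'", start,
                     prec_raw), call. = FALSE)
      }
      if (is.null(headers$`NUM PEAKS`)) {
        stop(sprintf("line %d: record '%s' is missing Num Peaks:", start,
                     headers$NAME), call. = FALSE)
      }
      declared <- suppressWarnings(as.integer(headers$`NUM PEAKS`))
      if (is.na(declared)) {
        stop(sprintf("line %d: non-numeric Num Peaks '%s'", start,
                     headers$`NUM PEAKS`), call. = FALSE)
      }
      if (declared != length(peak_lines)) {
        stop(sprintf(
          "line %d: record '%s' declares %d peaks but has %d peak lines",
          start, headers$NAME, declared, length(peak_lines)), call. = FALSE)
      }
      pk <- parse_peak_lines(peak_lines, peak_lnos)
      meta <- headers[setdiff(names(headers),
                              c("NAME", "PRECURSORMZ", "PRECURSOR_MZ",
                                "INCHIKEY", "NUM PEAKS"))]
      spectrum(pk$mz, pk$intensity, precursor_mz = prec,
               id = headers$NAME, inchikey = headers$INCHIKEY,
               metadata = meta)
    }, error = function(e) record_error(conditionMessage(e), lenient))
    if (!is.null(rec)) spectra[[length(spectra) + 1L]] <- rec
  }
  spectrum_library(spectra, source = path)
}
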