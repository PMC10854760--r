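#' Construct an MS/MS spectrum
#'
#' The unit every operation in this package transforms or compares: a
#' precursor m/z plus a fragment peak list sorted ascending by m/z. Peaks
#' sharing an identical m/z value are merged at construction time by summing
#' their intensities, so downstream peak matching always sees a strictly
#' increasing m/z vector.
#'
#' @param mz Numeric vector of fragment mass-to-charge values (Th, positive).
#' @param intensity Numeric vector of abundances (arbitrary units,
#'   non-negative), same length as `mz`.
#' @param precursor_mz Mass-to-charge of the fragmented precursor ion (Th), or
#'   `NA` when unknown.
#' @param id Opaque spectrum identifier.
#' @param inchikey Optional InChIKey (or its first-14 connectivity block) of
#'   the source molecule.
#' @param normalized Normalization state of the intensities: `"none"`,
#'   `"max"` or `"sum"`.
#' @param scheme Weighting provenance tag; `"raw"` for unweighted spectra.
#' @param metadata Named list of additional fields (charge, ion mode, ...)
#'   carried through untouched.
#'
#' @return An object of class `ms_spectrum`.
#' @export
#'
#' @examples
#' s <- spectrum(c(150, 100), c(5, 10), precursor_mz = 300, id = "ex1")
#' s$mz  # sorted: 100 150
spectrum <- function(mz, intensity, precursor_mz = NA_real_, id = "spectrum",
                     inchikey = NULL, normalized = "none", scheme = "raw",
                     metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("all m/z values must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.na(precursor_mz) && precursor_mz <= 0) {
    stop("`precursor_mz` must be > 0 when present", call. = FALSE)
  }
  normalized <- match.arg(normalized, c("none", "max", "sum"))
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(
    list(
      precursor_mz = as.numeric(precursor_mz),
      mz = mz,
      intensity = intensity,
      id = as.character(id),
      inchikey = inchikey,
      normalized = normalized,
      scheme = scheme,
      metadata = metadata
    ),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> %s: %d peaks, precursor m/z %s%s [normalized: %s, scheme: %s]\n",
    x$id, length(x$mz),
    if (is.na(x$precursor_mz)) "NA" else format(x$precursor_mz),
    if (is.null(x$inchikey)) "" else paste0(", inchikey ", x$inchikey),
    x$normalized, x$scheme
  ))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param x An `ms_spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "ms_spectrum"))
  length(x$mz)
}

is_spectrum <- function(x) inherits(x, "ms_spectrum")

#' Construct a spectrum library
#'
#' An ordered collection of [spectrum()] objects with unique identifiers.
#'
#' @param spectra List of `ms_spectrum` objects.
#' @param source Provenance string recorded on the library.
#' @return An object of class `ms_library` (also a list: `$spectra`,
#'   `$source`).
#' @export
spectrum_library <- function(spectra, source = "in-memory") {
  if (!is.list(spectra) || !all(vapply(spectra, is_spectrum, logical(1)))) {
    stop("`spectra` must be a list of ms_spectrum objects", call. = FALSE)
  }
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop("spectrum identifiers must be unique within a library; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(spectra) <- ids
  structure(list(spectra = spectra, source = source), class = "ms_library")
}

#' @export
print.ms_library <- function(x, ...) {
  cat(sprintf("<ms_library> %d spectra (source: %s)\n",
              length(x$spectra), x$source))
  invisible(x)
}

#' @export
length.ms_library <- function(x) length(x$spectra)

#' @export
`[[.ms_library` <- function(x, i) x$spectra[[i]]

#' Identifiers of the spectra in a library
#' @param x An `ms_library`.
#' @return Character vector of spectrum ids, in library order.
#' @export
library_ids <- function(x) {
  stopifnot(inherits(x, "ms_library"))
  unname(vapply(x$spectra, function(s) s$id, character(1)))
}

#' Normalize spectrum intensities
#'
#' Divides every intensity by the maximum (`mode = "max"`) or by the total
#' (`mode = "sum"`). Idempotent: normalizing an already-normalized spectrum is
#' the identity.
#'
#' @param x An `ms_spectrum` with at least one positive intensity.
#' @param mode `"max"` or `"sum"`.
#' @return The normalized `ms_spectrum` with its `normalized` flag set.
#' @export
normalize_spectrum <- function(x, mode = c("max", "sum")) {
  stopifnot(is_spectrum(x))
  mode <- match.arg(mode)
  if (length(x$intensity) == 0L || all(x$intensity == 0)) {
    stop("cannot normalize a spectrum whose intensities are all zero",
         call. = FALSE)
  }
  div <- if (mode == "max") max(x$intensity) else sum(x$intensity)
  x$intensity <- x$intensity / div
  x$normalized <- mode
  x
}

#' Pre-similarity spectrum filtering rules
#'
#' Bundles the thresholds applied by [filter_spectrum()]. Any rule can be
#' disabled: set `precursor_exclusion = 0`, `min_relative_intensity = 0`,
#' `min_peaks = 0`, `require_precursor = FALSE`.
#'
#' @param precursor_exclusion Remove peaks within this many Th of the
#'   precursor m/z (default 1.5).
#' @param min_relative_intensity Remove peaks below this fraction of the
#'   maximum intensity (default 0.001).
#' @param min_peaks Reject spectra with fewer remaining peaks (default 5).
#' @param require_precursor Reject spectra lacking a precursor m/z.
#' @return A `filter_config` list.
#' @export
filter_config <- function(precursor_exclusion = 1.5,
                          min_relative_intensity = 0.001,
                          min_peaks = 5L,
                          require_precursor = TRUE) {
  stopifnot(precursor_exclusion >= 0, min_relative_intensity >= 0,
            min_peaks >= 0)
  structure(
    list(
      precursor_exclusion = precursor_exclusion,
      min_relative_intensity = min_relative_intensity,
      min_peaks = as.integer(min_peaks),
      require_precursor = isTRUE(require_precursor)
    ),
    class = "filter_config"
  )
}

#' Read a filtering configuration from a flat key = value file
#'
#' One `key = value` pair per line (TOML-style scalars); `#` starts a comment.
#' Unknown keys are an error. Missing keys keep their [filter_config()]
#' defaults.
#'
#' @param path File path.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- filter_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown filter key: ", key, call. = FALSE)
    cfg[[key]] <- if (key == "require_precursor") {
      toupper(val) %in% c("TRUE", "YES", "1")
    } else if (key == "min_peaks") as.integer(val) else as.numeric(val)
  }
  do.call(filter_config, cfg)
}

#' Apply pre-similarity filtering to a spectrum
#'
#' Rules are applied in a fixed order: (1) remove peaks within
#' `precursor_exclusion` Th of the precursor m/z; (2) remove peaks below
#' `min_relative_intensity` of the maximum; (3) reject spectra with fewer than
#' `min_peaks` remaining peaks; (4) reject spectra lacking a precursor m/z
#' (when `require_precursor`). Rejection is a value, not an error.
#'
#' @param x An `ms_spectrum`.
#' @param config A [filter_config()].
#' @return The filtered `ms_spectrum`, or `NULL` when the spectrum is
#'   rejected.
#' @export
filter_spectrum <- function(x, config = filter_config()) {
  stopifnot(is_spectrum(x), inherits(config, "filter_config"))
  keep <- rep(TRUE, length(x$mz))
  if (config$precursor_exclusion > 0 && !is.na(x$precursor_mz)) {
    keep <- keep &
      abs(x$mz - x$precursor_mz) > config$precursor_exclusion
  }
  if (config$min_relative_intensity > 0 && any(keep)) {
    mx <- max(x$intensity[keep])
    if (mx > 0) {
      keep <- keep & x$intensity >= config$min_relative_intensity * mx
    }
  }
  x$mz <- x$mz[keep]
  x$intensity <- x$intensity[keep]
  if (length(x$mz) < config$min_peaks) return(NULL)
  if (config$require_precursor && is.na(x$precursor_mz)) return(NULL)
  x
}

#' Filter every spectrum in a library
#'
#' @param x An `ms_library`.
#' @param config A [filter_config()].
#' @return An `ms_library` containing the spectra that survived
#'   [filter_spectrum()]; rejected spectra are dropped.
#' @export
filter_library <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "ms_library"))
  kept <- Filter(Negate(is.null),
                 lapply(x$spectra, filter_spectrum, config = config))
  spectrum_library(unname(kept), source = x$source)
}

#' First-14 connectivity block of an InChIKey
#'
#' Two spectra of the same two-dimensional structure share the first 14
#' characters of their InChIKeys; library-search true positives are defined by
#' equality of this block.
#'
#' @param key InChIKey string (at least 14 characters).
#' @return The uppercased 14-character prefix.
#' @export
#'
#' @examples
#' inchikey14("BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
inchikey14 <- function(key) {
  if (!is.character(key) || length(key) != 1L || is.na(key)) {
    stop("`key` must be a single string", call. = FALSE)
  }
  if (nchar(key) < 14L) {
    stop("InChIKey must have at least 14 characters, got ", nchar(key),
         call. = FALSE)
  }
  toupper(substr(key, 1L, 14L))
}
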