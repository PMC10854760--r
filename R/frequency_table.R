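#' Build an m/z occurrence frequency table
#'
#' Tabulates, over a reference library, the fraction of spectra containing at
#' least one peak in each m/z bin. Bins are `resolution` Th wide (default
#' 0.1, i.e. m/z rounded to one decimal place); the bin key is the integer
#' `round(mz / resolution)` so the rounding is exact on an integer grid and
#' immune to binary-decimal drift. A spectrum contributes at most 1 to any
#' bin's count no matter how many of its peaks fall in the bin, so every
#' relative frequency lies in (0, 1].
#'
#' @param library A non-empty `ms_library` (the reference library).
#' @param resolution Bin width in Th.
#' @param unseen_policy What [mz_frequency()] returns for a bin absent from
#'   the table: `"floor"` (the smallest nonzero relative frequency observed;
#'   default), `"zero"`, or `"one"`.
#' @return An object of class `mz_frequency_table`.
#' @export
build_frequency_table <- function(library, resolution = 0.1,
                                  unseen_policy = c("floor", "zero", "one")) {
  stopifnot(inherits(library, "ms_library"))
  unseen_policy <- match.arg(unseen_policy)
  if (length(library$spectra) == 0L) {
    stop("cannot build a frequency table from an empty library",
         call. = FALSE)
  }
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("`resolution` must be a positive bin width in Th", call. = FALSE)
  }
  per_spectrum_bins <- lapply(library$spectra, function(s) {
    unique(as.integer(round(s$mz / resolution)))
  })
  tab <- table(unlist(per_spectrum_bins))
  bin_index <- as.integer(names(tab))
  o <- order(bin_index)
  n_spectra <- length(library$spectra)
  counts <- as.integer(tab)[o]
  structure(
    list(
      resolution = resolution,
      bin_index = bin_index[o],
      count = counts,
      n_spectra = n_spectra,
      floor = min(counts) / n_spectra,
      unseen_policy = unseen_policy
    ),
    class = "mz_frequency_table"
  )
}

#' @export
print.mz_frequency_table <- function(x, ...) {
  cat(sprintf(
    "<mz_frequency_table> %d bins at %.3g Th over %d spectra (floor %.4g, unseen: %s)\n",
    length(x$bin_index), x$resolution, x$n_spectra, x$floor,
    x$unseen_policy))
  invisible(x)
}

#' Look up relative m/z occurrence frequencies
#'
#' Returns `count / n_spectra` for the bin containing each query m/z. A bin
#' never seen in the reference library is handled by the table's
#' `unseen_policy`: the default `"floor"` returns the table's smallest
#' nonzero frequency, keeping unseen peaks down-weighted but alive under
#' frequency weighting (a zero would annihilate them).
#'
#' @param table An `mz_frequency_table`.
#' @param mz Numeric vector of query m/z values (Th, positive).
#' @return Numeric vector of relative frequencies, one per query.
#' @export
mz_frequency <- function(table, mz) {
  stopifnot(inherits(table, "mz_frequency_table"))
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("query m/z values must be finite and > 0", call. = FALSE)
  }
  idx <- match(as.integer(round(mz / table$resolution)), table$bin_index)
  out <- table$count[idx] / table$n_spectra
  unseen_value <- switch(table$unseen_policy,
                         floor = table$floor, zero = 0, one = 1)
  out[is.na(idx)] <- unseen_value
  out
}

#' Save a frequency table as TSV
#'
#' Writes a `# n_spectra=<N> resolution=<r>` metadata comment line followed
#' by tab-separated columns `mz_bin`, `count`, `relative_frequency`.
#' [load_frequency_table()] of the result reproduces the table exactly.
#'
#' @param table An `mz_frequency_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "mz_frequency_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# n_spectra=%d resolution=%.17g unseen_policy=%s",
                     table$n_spectra, table$resolution, table$unseen_policy),
             con)
  writeLines("mz_bin\tcount\trelative_frequency", con)
  writeLines(sprintf("%.17g\t%d\t%.17g",
                     table$bin_index * table$resolution,
                     table$count,
                     table$count / table$n_spectra),
             con)
  invisible(path)
}

#' Load a frequency table written by [save_frequency_table()]
#'
#' @param path TSV file path.
#' @return An `mz_frequency_table`.
#' @export
load_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1], "#")) {
    stop("line 1: expected '# n_spectra=... resolution=...' metadata comment",
         call. = FALSE)
  }
  meta_get <- function(key) {
    m <- regmatches(lines[1],
                    regexpr(paste0(key, "=[^ ]+"), lines[1]))
    if (length(m) == 0) {
      stop("line 1: metadata comment is missing ", key, call. = FALSE)
    }
    sub(paste0(key, "="), "", m)
  }
  n_spectra <- as.integer(meta_get("n_spectra"))
  resolution <- as.numeric(meta_get("resolution"))
  policy <- tryCatch(meta_get("unseen_policy"), error = function(e) "floor")
  if (is.na(n_spectra) || is.na(resolution)) {
    stop("line 1: non-numeric n_spectra or resolution", call. = FALSE)
  }
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("mz_bin", "count", "relative_frequency"))) {
    stop("line 2: expected header 'mz_bin\tcount\trelative_frequency'",
         call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 3 || anyNA(suppressWarnings(as.numeric(p)))) {
      stop(sprintf("line %d: malformed row '%s'", i + 2L, body[i]),
           call. = FALSE)
    }
  }
  mz_bin <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  count <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  if (any(count != round(count))) {
    stop("counts must be integers", call. = FALSE)
  }
  count <- as.integer(count)
  bin_index <- as.integer(round(mz_bin / resolution))
  o <- order(bin_index)
  structure(
    list(
      resolution = resolution,
      bin_index = bin_index[o],
      count = count[o],
      n_spectra = n_spectra,
      floor = min(count) / n_spectra,
      unseen_policy = policy
    ),
    class = "mz_frequency_table"
  )
}
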