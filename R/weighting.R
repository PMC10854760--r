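#' Classic intensity/mass-power weighting
#'
#' The historical family of weighting transforms: each peak intensity `I` at
#' mass `mz` becomes `I^n * mz^m`. Operates on raw (un-normalized)
#' intensities, as in the original formulations; peak m/z values are never
#' changed and no renormalization happens here (probability-based metrics
#' renormalize afterwards).
#'
#' @param x An `ms_spectrum` with non-negative intensities.
#' @param n Intensity exponent.
#' @param m m/z exponent.
#' @return The weighted `ms_spectrum`.
#' @export
#'
#' @examples
#' s <- spectrum(100, 4, precursor_mz = 200)
#' classic_weight(s, n = 0.5, m = 0.5)$intensity  # sqrt(4) * sqrt(100) = 20
classic_weight <- function(x, n, m) {
  stopifnot(is_spectrum(x))
  if (any(x$intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  x$intensity <- x$intensity^n * x$mz^m
  x$scheme <- sprintf("classic(n=%g,m=%g)", n, m)
  x
}

#' Frequency-aware low-intensity weighting
#'
#' The proposed transform: intensities are max-normalized, compressed by a
#' small exponent so low peaks are amplified relative to the base peak, and
#' multiplied by the relative occurrence frequency of their m/z value in a
#' reference library: `(I / I_max)^n * f(mz)^freq_exp`, with defaults
#' `n = 0.25` and `freq_exp = 0.25`. Frequent fragment masses are up-weighted;
#' rare ones down-weighted.
#'
#' @param x An `ms_spectrum` with a positive maximum intensity.
#' @param table An `mz_frequency_table` built from a reference library.
#' @param n Intensity exponent (applied to the max-normalized intensity).
#' @param freq_exp Exponent on the relative m/z frequency.
#' @return The weighted `ms_spectrum`.
#' @export
frequency_weight <- function(x, table, n = 0.25, freq_exp = 0.25) {
  stopifnot(is_spectrum(x), inherits(table, "mz_frequency_table"))
  if (length(x$intensity) == 0L || max(x$intensity) <= 0) {
    stop("spectrum must have a positive maximum intensity", call. = FALSE)
  }
  rel <- x$intensity / max(x$intensity)
  x$intensity <- rel^n * mz_frequency(table, x$mz)^freq_exp
  x$normalized <- "none"
  x$scheme <- sprintf("frequency(n=%g,freq_exp=%g)", n, freq_exp)
  x
}

#' Entropy-conditional intensity weighting
#'
#' Weighting conditioned on the spectral entropy `S` (in nats) of the
#' sum-normalized spectrum: spectra with `S >= 3` are left unchanged; below
#' that, every intensity is raised to the power `0.25 * (1 + S)`. The
#' exponent reaches 1 exactly at `S = 3`, so the transform is continuous at
#' the threshold.
#'
#' @param x A non-empty `ms_spectrum`.
#' @return The weighted `ms_spectrum`.
#' @export
entropy_weight <- function(x) {
  stopifnot(is_spectrum(x))
  s <- spectral_entropy(x)
  if (s < 3) {
    x$intensity <- x$intensity^(0.25 * (1 + s))
    x$normalized <- "none"
  }
  x$scheme <- sprintf("entropy(S=%.4f)", s)
  x
}

#' Binarize peak intensities
#'
#' Sets every positive intensity to 1 and drops zero-intensity peaks, leaving
#' only peak presence/absence. Idempotent.
#'
#' @param x An `ms_spectrum`.
#' @return The binarized `ms_spectrum`.
#' @export
binarize <- function(x) {
  stopifnot(is_spectrum(x))
  keep <- x$intensity > 0
  x$mz <- x$mz[keep]
  x$intensity <- rep(1, sum(keep))
  x$normalized <- "none"
  x$scheme <- "binarize"
  x
}

# Preset registry. Exponents for the classic schemes follow the values
# reported for each author's formulation; "proposed" is the frequency-aware
# scheme with fourth-root compression of the max-normalized intensity.
scheme_presets <- list(
  sokolow        = list(mode = "classic", n = 0.5,  m = 0.5),
  stein_scott    = list(mode = "classic", n = 0.6,  m = 3),
  horai          = list(mode = "classic", n = 0.5,  m = 2),
  kim            = list(mode = "classic", n = 0.53, m = 1.3),
  intensity_only = list(mode = "classic", n = 0.5,  m = 0),
  proposed       = list(mode = "frequency", n = 0.25, freq_exp = 0.25,
                        normalization = "max"),
  entropy        = list(mode = "entropy"),
  binarize       = list(mode = "binarize"),
  unweighted     = list(mode = "identity")
)

#' Weighting scheme objects
#'
#' `weight_scheme()` resolves a preset name (see [list_schemes()]) or a
#' `"custom:n=..,m=.."` string into a parameter object that
#' [apply_scheme()] dispatches on. Exactly one mode is active per scheme:
#' classic (`I^n * mz^m`), frequency (`(I/I_max)^n * f(mz)^freq_exp`),
#' entropy-conditional, binarize, or identity.
#'
#' @param name Preset name, or `"custom:n=<n>,m=<m>"` for an ad-hoc classic
#'   scheme.
#' @return A `weight_scheme` object.
#' @export
#'
#' @examples
#' weight_scheme("sokolow")
#' weight_scheme("custom:n=0.3,m=1")
weight_scheme <- function(name) {
  if (inherits(name, "weight_scheme")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (startsWith(name, "custom:")) {
    spec <- strsplit(sub("^custom:", "", name), ",", fixed = TRUE)[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2)))
    if (!setequal(keys, c("n", "m")) || anyNA(vals)) {
      stop("custom schemes take the form 'custom:n=<num>,m=<num>'",
           call. = FALSE)
    }
    p <- list(mode = "classic", n = vals[keys == "n"], m = vals[keys == "m"])
  } else {
    p <- scheme_presets[[name]]
    if (is.null(p)) {
      stop("unknown weighting scheme '", name, "'; available: ",
           paste(names(scheme_presets), collapse = ", "), call. = FALSE)
    }
  }
  structure(c(list(name = name), p), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  pars <- x[setdiff(names(x), c("name", "mode"))]
  cat(sprintf("<weight_scheme> %s [%s]%s\n", x$name, x$mode,
              if (length(pars)) paste0(" ",
                paste(names(pars), unlist(pars), sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

#' Names of the built-in weighting schemes
#' @return Character vector of preset names accepted by [weight_scheme()].
#' @export
list_schemes <- function() names(scheme_presets)

#' Apply a weighting scheme to a spectrum
#'
#' Dispatches to [classic_weight()], [frequency_weight()],
#' [entropy_weight()], [binarize()], or the identity, according to the
#' scheme's mode. The result carries the scheme name as its provenance tag.
#'
#' @param x An `ms_spectrum`.
#' @param scheme A [weight_scheme()] or preset name.
#' @param table An `mz_frequency_table`; required by frequency-mode schemes.
#' @return The weighted `ms_spectrum`.
#' @export
apply_scheme <- function(x, scheme, table = NULL) {
  scheme <- weight_scheme(scheme)
  out <- switch(scheme$mode,
    classic = classic_weight(x, n = scheme$n, m = scheme$m),
    frequency = {
      if (is.null(table)) {
        stop("scheme '", scheme$name,
             "' requires a frequency table (see build_frequency_table)",
             call. = FALSE)
      }
      frequency_weight(x, table, n = scheme$n, freq_exp = scheme$freq_exp)
    },
    entropy = entropy_weight(x),
    binarize = binarize(x),
    identity = x,
    stop("unknown scheme mode: ", scheme$mode, call. = FALSE)
  )
  out$scheme <- scheme$name
  out
}
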