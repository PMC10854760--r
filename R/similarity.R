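#' Tolerance-based peak matching between two spectra
#'
#' Candidate pairs are all peak pairs (i, j) with `|mz_a - mz_b| <=
#' tolerance` (direct), plus, when `allow_shift = TRUE`, pairs whose m/z
#' difference equals the precursor m/z difference to within the tolerance
#' (shifted) -- the alignment step that lets modified cosine match fragments
#' carried across a single mass modification. Candidates are accepted
#' greedily in descending order of intensity product `I_a * I_b`
#' (tie-breaks: smaller residual |delta mz|, then smaller index in A, then in
#' B), each peak used at most once. A pair satisfying both rules counts as
#' direct.
#'
#' @param a,b Non-empty `ms_spectrum` objects; both need a precursor m/z when
#'   `allow_shift = TRUE`.
#' @param tolerance Fragment m/z tolerance in Th.
#' @param allow_shift Also admit precursor-shifted candidate pairs.
#' @return An object of class `peak_match`: a list with `matches` (data frame
#'   of `index_a`, `index_b`, `kind`), `tolerance` and `precursor_diff`
#'   (`precursor_mz(a) - precursor_mz(b)`, `NA` unless shifting).
#' @export
match_peaks <- function(a, b, tolerance = 0.1, allow_shift = FALSE) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  if (n_peaks(a) == 0L || n_peaks(b) == 0L) {
    stop("both spectra must be non-empty", call. = FALSE)
  }
  pdiff <- NA_real_
  if (allow_shift) {
    if (is.na(a$precursor_mz) || is.na(b$precursor_mz)) {
      stop("shifted matching requires a precursor m/z on both spectra",
           call. = FALSE)
    }
    pdiff <- a$precursor_mz - b$precursor_mz
  }
  d <- outer(a$mz, b$mz, "-")
  direct <- abs(d) <= tolerance
  cand_i <- integer(0); cand_j <- integer(0)
  cand_kind <- character(0); cand_resid <- numeric(0)
  if (any(direct)) {
    w <- which(direct, arr.ind = TRUE)
    cand_i <- w[, 1]; cand_j <- w[, 2]
    cand_kind <- rep("direct", nrow(w))
    cand_resid <- abs(d[direct])
  }
  if (allow_shift) {
    shifted <- abs(d - pdiff) <= tolerance & !direct
    if (any(shifted)) {
      w <- which(shifted, arr.ind = TRUE)
      cand_i <- c(cand_i, w[, 1]); cand_j <- c(cand_j, w[, 2])
      cand_kind <- c(cand_kind, rep("shifted", nrow(w)))
      cand_resid <- c(cand_resid, abs(d[shifted] - pdiff))
    }
  }
  matches <- data.frame(index_a = integer(0), index_b = integer(0),
                        kind = character(0), stringsAsFactors = FALSE)
  if (length(cand_i)) {
    prod <- a$intensity[cand_i] * b$intensity[cand_j]
    o <- order(-prod, cand_resid, cand_i, cand_j)
    used_a <- logical(n_peaks(a)); used_b <- logical(n_peaks(b))
    sel <- integer(0)
    for (k in o) {
      if (!used_a[cand_i[k]] && !used_b[cand_j[k]]) {
        used_a[cand_i[k]] <- TRUE
        used_b[cand_j[k]] <- TRUE
        sel <- c(sel, k)
      }
    }
    matches <- data.frame(index_a = cand_i[sel], index_b = cand_j[sel],
                          kind = cand_kind[sel], stringsAsFactors = FALSE)
  }
  structure(list(matches = matches, tolerance = tolerance,
                 precursor_diff = pdiff),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("<peak_match> %d matches (%d shifted), tolerance %g Th\n",
              nrow(x$matches), sum(x$matches$kind == "shifted"),
              x$tolerance))
  invisible(x)
}

# Shared cosine kernel: matched intensity products over full-spectrum norms.
cosine_from_matches <- function(a, b, mr) {
  na <- sqrt(sum(a$intensity^2))
  nb <- sqrt(sum(b$intensity^2))
  if (na == 0 || nb == 0) {
    stop("cosine is undefined for a zero-norm spectrum", call. = FALSE)
  }
  m <- mr$matches
  num <- sum(a$intensity[m$index_a] * b$intensity[m$index_b])
  min(max(num / (na * nb), 0), 1)
}

#' Cosine similarity between two spectra
#'
#' Sum of intensity products over directly matched peak pairs, divided by the
#' product of the full-spectrum Euclidean norms; clipped to \[0, 1\].
#'
#' @param a,b Non-empty `ms_spectrum` objects.
#' @param tolerance Fragment m/z tolerance in Th.
#' @return Similarity in \[0, 1\].
#' @export
cosine_score <- function(a, b, tolerance = 0.1) {
  cosine_from_matches(a, b, match_peaks(a, b, tolerance, allow_shift = FALSE))
}

#' Modified cosine similarity
#'
#' As [cosine_score()], but the peak matching also admits pairs offset by the
#' precursor mass difference, capturing shared substructure under a single
#' modification (the alignment used in molecular networking).
#'
#' @inheritParams cosine_score
#' @return Similarity in \[0, 1\].
#' @export
modified_cosine <- function(a, b, tolerance = 0.1) {
  if (is.na(a$precursor_mz) || is.na(b$precursor_mz)) {
    stop("modified cosine requires a precursor m/z on both spectra",
         call. = FALSE)
  }
  cosine_from_matches(a, b, match_peaks(a, b, tolerance, allow_shift = TRUE))
}

#' Spectral entropy
#'
#' Shannon entropy, in nats, of the sum-normalized intensities:
#' `S = -sum(p * log(p))`.
#'
#' @param x A non-empty `ms_spectrum` with positive total intensity.
#' @return Entropy in nats (`0` for a single peak, `log(n)` for `n` equal
#'   peaks).
#' @export
spectral_entropy <- function(x) {
  stopifnot(is_spectrum(x))
  if (n_peaks(x) == 0L) stop("spectrum is empty", call. = FALSE)
  tot <- sum(x$intensity)
  if (tot <= 0) stop("spectrum has zero total intensity", call. = FALSE)
  p <- x$intensity / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Probability-metric preamble: sum-normalize both spectra and match peaks
# directly at the tolerance.
prob_match <- function(a, b, tolerance) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  if (n_peaks(a) == 0L || n_peaks(b) == 0L) {
    stop("both spectra must be non-empty", call. = FALSE)
  }
  pa <- a$intensity / sum(a$intensity)
  qb <- b$intensity / sum(b$intensity)
  mr <- match_peaks(a, b, tolerance, allow_shift = FALSE)
  list(pa = pa, qb = qb, m = mr$matches)
}

#' Spectral entropy similarity
#'
#' Both spectra are sum-normalized; a merged spectrum is built in which each
#' matched pair contributes one atom of mass `(p_A + p_B) / 2` and every
#' unmatched peak enters at half weight. The similarity is
#' `1 - (2 * S_AB - S_A - S_B) / log(4)`, clipped to \[0, 1\]: identical
#' spectra give 1, fully disjoint spectra give 0.
#'
#' @inheritParams cosine_score
#' @return Similarity in \[0, 1\].
#' @export
entropy_similarity <- function(a, b, tolerance = 0.1) {
  pm <- prob_match(a, b, tolerance)
  free_a <- setdiff(seq_along(pm$pa), pm$m$index_a)
  free_b <- setdiff(seq_along(pm$qb), pm$m$index_b)
  merged <- c((pm$pa[pm$m$index_a] + pm$qb[pm$m$index_b]) / 2,
              pm$pa[free_a] / 2,
              pm$qb[free_b] / 2)
  s_ab <- shannon(merged)
  s_a <- shannon(pm$pa)
  s_b <- shannon(pm$qb)
  val <- 1 - (2 * s_ab - s_a - s_b) / log(4)
  min(max(val, 0), 1)
}

#' Fidelity similarity (Bhattacharyya coefficient)
#'
#' Sum of `sqrt(p_a * q_b)` over matched peak pairs of the sum-normalized
#' spectra.
#'
#' @inheritParams cosine_score
#' @return Similarity in \[0, 1\].
#' @export
fidelity_similarity <- function(a, b, tolerance = 0.1) {
  pm <- prob_match(a, b, tolerance)
  min(max(sum(sqrt(pm$pa[pm$m$index_a] * pm$qb[pm$m$index_b])), 0), 1)
}

#' Bhattacharya 1 similarity
#'
#' The squared-arccosine Bhattacharyya distance `D = acos(F)^2` of the
#' fidelity coefficient `F`, mapped to a similarity on \[0, 1\] by
#' `1 - D / (pi/2)^2` (`F` is clipped to \[0, 1\] before the arccosine to
#' absorb floating-point overshoot).
#'
#' @inheritParams cosine_score
#' @return Similarity in \[0, 1\].
#' @export
bhattacharya1_similarity <- function(a, b, tolerance = 0.1) {
  f <- fidelity_similarity(a, b, tolerance)
  d <- acos(min(max(f, 0), 1))^2
  min(max(1 - d / (pi / 2)^2, 0), 1)
}

# Pluggable metric registry. Built-ins are installed when the package is
# built; user metrics join them via register_metric().
.metric_registry <- new.env(parent = emptyenv())

register_builtin_metrics <- function() {
  assign("cosine", cosine_score, envir = .metric_registry)
  assign("modified_cosine", modified_cosine, envir = .metric_registry)
  assign("entropy", entropy_similarity, envir = .metric_registry)
  assign("fidelity", fidelity_similarity, envir = .metric_registry)
  assign("bhattacharya1", bhattacharya1_similarity, envir = .metric_registry)
}

register_builtin_metrics()

#' Register a similarity metric
#'
#' Adds a matched-peak scoring function to the metric registry, making it
#' callable through [similarity_score()] (and the command-line `pair` and
#' `search` subcommands) under the given name. Built-in names cannot be
#' overwritten.
#'
#' @param name Unused metric name.
#' @param fn Function with signature `function(a, b, tolerance)` returning a
#'   similarity in \[0, 1\].
#' @return `name`, invisibly.
#' @export
register_metric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (exists(name, envir = .metric_registry, inherits = FALSE)) {
    stop("metric '", name, "' is already registered", call. = FALSE)
  }
  assign(name, fn, envir = .metric_registry)
  invisible(name)
}

#' Names of the registered similarity metrics
#' @return Sorted character vector of metric names.
#' @export
list_metrics <- function() sort(ls(.metric_registry))

#' Score a spectrum pair with a registered metric
#'
#' @param a,b `ms_spectrum` objects.
#' @param metric Registered metric name (see [list_metrics()]).
#' @param tolerance Fragment m/z tolerance in Th.
#' @return Similarity in \[0, 1\].
#' @export
similarity_score <- function(a, b, metric = "cosine", tolerance = 0.1) {
  if (!exists(metric, envir = .metric_registry, inherits = FALSE)) {
    stop("unknown metric '", metric, "'; registered: ",
         paste(list_metrics(), collapse = ", "), call. = FALSE)
  }
  fn <- get(metric, envir = .metric_registry, inherits = FALSE)
  fn(a, b, tolerance)
}
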