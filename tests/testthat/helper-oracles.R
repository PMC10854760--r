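# Shared fixtures and independent brute-force oracles used across the suite.

spec <- function(mz, int, prec = NA_real_, id = "s", key = NULL) {
  spectrum(mz, int, precursor_mz = prec, id = id, inchikey = key)
}

# A random spectrum on a coarse m/z grid (collisions likely, exercising the
# matcher's conflict resolution).
random_spectrum <- function(n_peaks, mz_min = 100, mz_max = 110,
                           grid = 0.25, prec = NULL) {
  mz <- sort(sample(seq(mz_min, mz_max, by = grid), n_peaks)) +
    stats::runif(n_peaks, -0.02, 0.02)
  if (is.null(prec)) prec <- stats::runif(1, 200, 500)
  spectrum(mz, stats::rlnorm(n_peaks), precursor_mz = prec,
           id = paste0("r", sample.int(1e9, 1)))
}

# Candidate peak pairs under the direct and (optionally) shifted rules;
# independent of match_peaks internals.
oracle_candidates <- function(a, b, tolerance, allow_shift = FALSE) {
  cand <- NULL
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      direct <- abs(a$mz[i] - b$mz[j]) <= tolerance
      shifted <- allow_shift &&
        abs((a$mz[i] - b$mz[j]) - (a$precursor_mz - b$precursor_mz)) <=
          tolerance
      if (direct || shifted) cand <- rbind(cand, c(i, j))
    }
  }
  cand
}

# Exhaustive optimal one-to-one assignment: maximum achievable sum of
# intensity products over the candidate pairs. Recursion over A's peaks
# (feasible for <= 6 peaks per side).
oracle_optimal_product_sum <- function(a, b, tolerance,
                                       allow_shift = FALSE) {
  cand <- oracle_candidates(a, b, tolerance, allow_shift)
  if (is.null(cand)) return(0)
  options_for <- lapply(seq_along(a$mz),
                        function(i) cand[cand[, 1] == i, 2])
  best <- 0
  recurse <- function(i, used_b, total) {
    if (i > length(a$mz)) {
      best <<- max(best, total)
      return(invisible())
    }
    recurse(i + 1, used_b, total)  # leave peak i unmatched
    for (j in options_for[[i]]) {
      if (!used_b[j]) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, total + a$intensity[i] * b$intensity[j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(b$mz)), 0)
  best
}

greedy_product_sum <- function(a, b, tolerance, allow_shift = FALSE) {
  m <- match_peaks(a, b, tolerance, allow_shift)$matches
  sum(a$intensity[m$index_a] * b$intensity[m$index_b])
}

# O(n^2) concordant-pair AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force F-beta scan over the same candidate grid as optimal_cutoff.
oracle_best_cutoff <- function(scores, labels, beta = 1) {
  cand <- sort(unique(c(scores, seq(0, 1, by = 0.01))))
  best <- c(cutoff = NA_real_, fbeta = -1)
  for (cc in cand) {
    pred <- scores >= cc
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    denom <- (1 + beta^2) * tp + beta^2 * fn + fp
    f <- if (denom == 0) 0 else (1 + beta^2) * tp / denom
    if (f > best["fbeta"] + 1e-12) best <- c(cutoff = cc, fbeta = f)
  }
  best
}

# Small deterministic library for I/O and frequency-table tests.
toy_library <- function(n = 4) {
  spectrum_library(lapply(seq_len(n), function(i) {
    spec(c(100.04 + i / 100, 150.5, 200 + i), c(1, 2, 3) * i,
         prec = 300 + i, id = paste0("toy", i),
         key = paste0(paste(rep(LETTERS[i], 14), collapse = ""),
                      "-UHFFFAOYSA-N"))
  }), source = "toy")
}
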