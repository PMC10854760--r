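#' Tanimoto coefficient of two fingerprint bit vectors
#'
#' `|a AND b| / |a OR b|` for equal-length 0/1 (or logical) vectors; the
#' standard structural-similarity proxy for molecular fingerprints. Two
#' all-zero vectors are defined as similarity 1 (with a warning, since no
#' bits carry information).
#'
#' @param a,b Equal-length bit vectors (logical or 0/1 numeric).
#' @return Coefficient in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints must have equal length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0) {
    warning("both fingerprints are all-zero; returning 1", call. = FALSE)
    return(1)
  }
  sum(a & b) / union
}

#' Binary structural-similarity labels from Tanimoto coefficients
#'
#' Label 1 marks structurally similar pairs: `tanimoto > threshold` under the
#' default strict rule. `boundary = "gte"` counts the boundary as positive
#' instead.
#'
#' @param tanimoto Numeric vector of Tanimoto coefficients in \[0, 1\].
#' @param threshold Similarity threshold in (0, 1); 0.7 is the conventional
#'   choice, 0.8 a common sensitivity setting.
#' @param boundary `"strict"` (`>`) or `"gte"` (`>=`).
#' @return Integer vector of 0/1 labels.
#' @export
label_pairs <- function(tanimoto, threshold = 0.7,
                        boundary = c("strict", "gte")) {
  stopifnot(threshold > 0, threshold < 1)
  boundary <- match.arg(boundary)
  if (boundary == "strict") as.integer(tanimoto > threshold)
  else as.integer(tanimoto >= threshold)
}

fbeta_from_counts <- function(tp, fp, fn, beta) {
  denom <- (1 + beta^2) * tp + beta^2 * fn + fp
  ifelse(denom == 0, 0, (1 + beta^2) * tp / denom)
}

#' Optimal F-beta score cutoff for a score/label set
#'
#' Scans candidate cutoffs (the sorted unique scores plus a 0.01-step grid on
#' \[0, 1\]) and returns the cutoff maximizing the F-beta score of the rule
#' "score >= cutoff is predicted positive". Ties go to the lowest cutoff.
#' `beta = 1` gives the F1 optimum; `beta = 2` favors recall.
#'
#' @param scores Numeric similarity scores in \[0, 1\].
#' @param labels 0/1 labels, both classes present.
#' @param beta F-beta parameter.
#' @return List with `cutoff` and `fbeta`.
#' @export
optimal_cutoff <- function(scores, labels, beta = 1) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to optimize a cutoff", call. = FALSE)
  }
  cand <- sort(unique(c(scores, seq(0, 1, by = 0.01))))
  n_pos <- sum(labels == 1)
  # sort scores descending once; cumulative positives give TP at any cutoff
  o <- order(scores, decreasing = TRUE)
  s_sorted <- scores[o]
  cum_tp <- cumsum(labels[o] == 1L)
  n_pred <- vapply(cand, function(cc) sum(s_sorted >= cc), integer(1))
  tp <- ifelse(n_pred == 0L, 0L, cum_tp[pmax(n_pred, 1L)])
  fp <- n_pred - tp
  fn <- n_pos - tp
  f <- fbeta_from_counts(tp, fp, fn, beta)
  best <- which.max(f)  # which.max returns the first (lowest cutoff) on ties
  list(cutoff = cand[best], fbeta = f[best])
}

#' Contingency table at a score cutoff
#'
#' Counts of true/false positives/negatives under the rule "score >= cutoff
#' is predicted positive" (boundary counted positive, consistent with
#' [optimal_cutoff()]).
#'
#' @param scores Numeric similarity scores.
#' @param labels 0/1 labels.
#' @param cutoff Decision cutoff in \[0, 1\].
#' @return Named integer vector `c(tp, fp, fn, tn)`; the cells sum to
#'   `length(scores)`.
#' @export
contingency <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels), cutoff >= 0, cutoff <= 1)
  labels <- as.integer(labels)
  pred <- scores >= cutoff
  c(tp = sum(pred & labels == 1L),
    fp = sum(pred & labels == 0L),
    fn = sum(!pred & labels == 1L),
    tn = sum(!pred & labels == 0L))
}

#' Kullback-Leibler divergence between two score samples
#'
#' Histograms both samples on \[0, 1\] with `n_bins` equal bins, applies
#' add-epsilon smoothing before normalizing, and returns the discrete
#' `KL(P_scores || Q_reference)` in nats. Used to quantify how closely a
#' similarity-score distribution resembles the reference Tanimoto
#' distribution; note KL is directional (`KL(P||Q) != KL(Q||P)` in general).
#'
#' @param scores Sample whose distribution is tested (P).
#' @param reference_scores Reference sample (Q).
#' @param n_bins Number of histogram bins (>= 2).
#' @param eps Smoothing constant added to every bin count.
#' @return KL divergence in nats (>= 0; 0 for identical samples).
#' @export
kl_to_reference <- function(scores, reference_scores, n_bins = 20,
                            eps = 1e-10) {
  if (n_bins < 2) stop("`n_bins` must be at least 2", call. = FALSE)
  if (length(scores) == 0 || length(reference_scores) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = n_bins)
  }
  p <- bin(scores) + eps
  q <- bin(reference_scores) + eps
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Rank-based AUC-ROC
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a random
#' positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precursor-windowed spectral library search
#'
#' For each query spectrum, reference spectra whose precursor m/z lies within
#' `ppm` parts-per-million of the query precursor
#' (`|prec_q - prec_l| <= ppm * prec_q / 1e6`) are scored with the chosen
#' metric after applying the weighting scheme to both spectra, then ranked by
#' descending score (ties: ascending |delta ppm|, then library identifier).
#' A hit is a true positive when both spectra carry an InChIKey and their
#' first-14 blocks agree.
#'
#' @param queries,library `ms_library` objects; every spectrum needs a
#'   precursor m/z.
#' @param ppm Precursor window half-width in parts per million.
#' @param metric Registered similarity metric name.
#' @param scheme Weighting scheme (name or [weight_scheme()]).
#' @param table `mz_frequency_table` for frequency-mode schemes.
#' @param tolerance Fragment m/z tolerance in Th.
#' @return An object of class `search_results`: list with `hits` (data frame
#'   `query_id`, `rank`, `library_id`, `score`, `delta_ppm`, `is_tp`),
#'   `query_ids` (all queries, including those with zero candidates) and
#'   `params`.
#' @export
library_search <- function(queries, library, ppm = 10,
                           metric = "modified_cosine",
                           scheme = "unweighted", table = NULL,
                           tolerance = 0.1) {
  stopifnot(inherits(queries, "ms_library"), inherits(library, "ms_library"))
  scheme <- weight_scheme(scheme)
  lib_prec <- vapply(library$spectra, function(s) s$precursor_mz, numeric(1))
  q_prec <- vapply(queries$spectra, function(s) s$precursor_mz, numeric(1))
  if (anyNA(lib_prec) || anyNA(q_prec)) {
    stop("library search requires a precursor m/z on every spectrum",
         call. = FALSE)
  }
  lib_ids <- library_ids(library)
  lib_weighted <- lapply(library$spectra, apply_scheme, scheme = scheme,
                         table = table)
  lib_key <- vapply(library$spectra, function(s) {
    if (is.null(s$inchikey)) NA_character_ else inchikey14(s$inchikey)
  }, character(1))
  rows <- vector("list", length(queries$spectra))
  for (qi in seq_along(queries$spectra)) {
    q <- queries$spectra[[qi]]
    delta_ppm <- (q_prec[qi] - lib_prec) / q_prec[qi] * 1e6
    cand <- which(abs(delta_ppm) <= ppm)
    if (length(cand) == 0L) next
    qw <- apply_scheme(q, scheme, table = table)
    sc <- vapply(cand, function(li) {
      similarity_score(qw, lib_weighted[[li]], metric = metric,
                       tolerance = tolerance)
    }, numeric(1))
    q_key <- if (is.null(q$inchikey)) NA_character_ else inchikey14(q$inchikey)
    is_tp <- if (is.na(q_key)) rep(NA, length(cand)) else {
      ifelse(is.na(lib_key[cand]), NA, lib_key[cand] == q_key)
    }
    o <- order(-sc, abs(delta_ppm[cand]), lib_ids[cand])
    rows[[qi]] <- data.frame(
      query_id = q$id,
      rank = seq_along(cand),
      library_id = lib_ids[cand][o],
      score = sc[o],
      delta_ppm = delta_ppm[cand][o],
      is_tp = is_tp[o],
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(hits)) {
    hits <- data.frame(query_id = character(0), rank = integer(0),
                       library_id = character(0), score = numeric(0),
                       delta_ppm = numeric(0), is_tp = logical(0),
                       stringsAsFactors = FALSE)
  }
  structure(
    list(hits = hits, query_ids = library_ids(queries),
         params = list(ppm = ppm, metric = metric, scheme = scheme$name,
                       tolerance = tolerance)),
    class = "search_results"
  )
}

#' @export
print.search_results <- function(x, ...) {
  cat(sprintf(
    "<search_results> %d queries, %d hits (ppm %g, metric %s, scheme %s)\n",
    length(x$query_ids), nrow(x$hits), x$params$ppm, x$params$metric,
    x$params$scheme))
  invisible(x)
}

#' Average precision at K over ranked search results
#'
#' Per query: the fraction of true positives among the top `min(k, returned)`
#' hits; queries that returned no candidates contribute 0 and are counted.
#' Hits with unknown truth (`is_tp = NA`) count as false.
#'
#' @param results A `search_results` object.
#' @param k Rank depth (>= 1).
#' @return Average precision at K over all queries.
#' @export
precision_at_k <- function(results, k) {
  stopifnot(inherits(results, "search_results"), k >= 1)
  per_query <- vapply(results$query_ids, function(qid) {
    h <- results$hits[results$hits$query_id == qid, , drop = FALSE]
    if (nrow(h) == 0L) return(0)
    top <- h[h$rank <= min(k, nrow(h)), , drop = FALSE]
    sum(top$is_tp %in% TRUE) / nrow(top)
  }, numeric(1))
  mean(per_query)
}

#' Queries without a confident match
#'
#' Counts, over all queries (including those with zero candidates), how many
#' returned no hit scoring strictly above `score_threshold`, and how many
#' returned no true-positive hit above it.
#'
#' @param results A `search_results` object.
#' @param score_threshold Similarity threshold in \[0, 1\].
#' @return Named integer vector `c(no_match, no_true_positive_match)`.
#' @export
count_no_match_queries <- function(results, score_threshold = 0.5) {
  stopifnot(inherits(results, "search_results"),
            score_threshold >= 0, score_threshold <= 1)
  counts <- vapply(results$query_ids, function(qid) {
    h <- results$hits[results$hits$query_id == qid, , drop = FALSE]
    above <- h$score > score_threshold
    c(no_match = !any(above),
      no_tp = !any(above & h$is_tp %in% TRUE))
  }, logical(2))
  c(no_match = sum(counts["no_match", ]),
    no_true_positive_match = sum(counts["no_tp", ]))
}

#' Dominant-peak profile of a spectrum
#'
#' Reports the peak count and the share of total intensity carried by the
#' largest peak -- the two features that flag the regime where intensity
#' weighting hurts: spectra with a single dominant peak (share above 0.7) or
#' very few peaks tend to lose score under weighting when their dominant peak
#' is already well aligned.
#'
#' @param x A non-empty `ms_spectrum`.
#' @param share_threshold Dominance threshold on the max-intensity share.
#' @param min_peaks Peak count below which weighting is not advised.
#' @return List with `n_peaks`, `max_share`, and `advise_weighting` (FALSE
#'   when the spectrum is dominant-peaked or peak-poor).
#' @export
dominant_peak_profile <- function(x, share_threshold = 0.7, min_peaks = 5L) {
  stopifnot(is_spectrum(x))
  if (n_peaks(x) == 0L) stop("spectrum is empty", call. = FALSE)
  share <- max(x$intensity) / sum(x$intensity)
  list(n_peaks = n_peaks(x),
       max_share = share,
       advise_weighting = share <= share_threshold &&
         n_peaks(x) >= min_peaks)
}
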