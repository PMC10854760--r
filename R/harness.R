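# Benchmark harnesses tying the generator, weighting schemes and metrics
# together: pair scoring for the alignment task and scheme comparison for the
# library-search task.

#' Score every benchmark pair with one metric and weighting scheme
#'
#' @param bench A `synthetic_benchmark` (or any list with `pairs` and
#'   `pair_spectra` in the same layout).
#' @param metric Registered similarity metric name.
#' @param scheme Weighting scheme name or [weight_scheme()].
#' @param table `mz_frequency_table` for frequency-mode schemes; when `NULL`
#'   and the scheme needs one, it is built from `bench$reference`.
#' @param tolerance Fragment m/z tolerance in Th.
#' @return Numeric score vector aligned with the rows of `bench$pairs`.
#' @export
score_pairs <- function(bench, metric = "modified_cosine",
                        scheme = "unweighted", table = NULL,
                        tolerance = 0.1) {
  scheme <- weight_scheme(scheme)
  if (is.null(table) && identical(scheme$mode, "frequency")) {
    table <- build_frequency_table(bench$reference)
  }
  cache <- new.env(parent = emptyenv())
  weighted <- function(id) {
    if (!exists(id, envir = cache, inherits = FALSE)) {
      assign(id, apply_scheme(bench$pair_spectra[[id]], scheme,
                              table = table), envir = cache)
    }
    get(id, envir = cache, inherits = FALSE)
  }
  vapply(seq_len(nrow(bench$pairs)), function(i) {
    similarity_score(weighted(bench$pairs$id_a[i]),
                     weighted(bench$pairs$id_b[i]),
                     metric = metric, tolerance = tolerance)
  }, numeric(1))
}

#' Alignment benchmark: spectral similarity versus structural similarity
#'
#' For each weighting scheme, scores all pairs with the metric, labels them
#' structurally similar when their Tanimoto coefficient exceeds
#' `tanimoto_threshold`, finds the F-beta-optimal score cutoff, tabulates the
#' contingency table at that cutoff, and computes the KL divergence of the
#' score distribution from the Tanimoto distribution.
#'
#' @param bench A `synthetic_benchmark`.
#' @param schemes Character vector of weighting scheme names to compare.
#' @param metric Registered similarity metric name.
#' @param table Frequency table for frequency-mode schemes (built from
#'   `bench$reference` when `NULL`).
#' @param tolerance Fragment m/z tolerance in Th.
#' @param tanimoto_threshold Structural-similarity label threshold.
#' @param beta F-beta parameter for cutoff optimization.
#' @param n_bins Histogram bins for the KL divergence.
#' @param stratum Restrict the evaluation to one stratum of `bench$pairs`
#'   (`"dominant"` / `"no_dominant"`), or `NULL` for all pairs.
#' @return An `alignment_report`: list with `table` (one row per scheme:
#'   `scheme`, `cutoff`, `fbeta`, `tp`, `fp`, `fn`, `tn`, `kl`), `scores`
#'   (named list of score vectors), `labels`, and the evaluation settings.
#' @export
alignment_benchmark <- function(bench,
                                schemes = c("unweighted", "proposed"),
                                metric = "modified_cosine", table = NULL,
                                tolerance = 0.1, tanimoto_threshold = 0.7,
                                beta = 1, n_bins = 20, stratum = NULL) {
  pairs <- bench$pairs
  keep <- if (is.null(stratum)) rep(TRUE, nrow(pairs))
          else pairs$stratum == stratum
  if (is.null(table) &&
      any(vapply(schemes,
                 function(s) identical(weight_scheme(s)$mode, "frequency"),
                 logical(1)))) {
    table <- build_frequency_table(bench$reference)
  }
  labels <- label_pairs(pairs$tanimoto[keep], tanimoto_threshold)
  scores <- list()
  rows <- lapply(schemes, function(sch) {
    sc <- score_pairs(bench, metric = metric, scheme = sch, table = table,
                      tolerance = tolerance)[keep]
    scores[[sch]] <<- sc
    opt <- optimal_cutoff(sc, labels, beta = beta)
    ct <- contingency(sc, labels, opt$cutoff)
    data.frame(scheme = sch, cutoff = opt$cutoff, fbeta = opt$fbeta,
               tp = ct[["tp"]], fp = ct[["fp"]], fn = ct[["fn"]],
               tn = ct[["tn"]],
               kl = kl_to_reference(sc, pairs$tanimoto[keep],
                                    n_bins = n_bins),
               stringsAsFactors = FALSE)
  })
  structure(
    list(table = do.call(rbind, rows), scores = scores, labels = labels,
         settings = list(metric = metric, tolerance = tolerance,
                         tanimoto_threshold = tanimoto_threshold,
                         beta = beta, n_bins = n_bins, stratum = stratum)),
    class = "alignment_report"
  )
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> metric %s, label: Tanimoto > %g%s\n",
              x$settings$metric, x$settings$tanimoto_threshold,
              if (is.null(x$settings$stratum)) ""
              else paste0(", stratum ", x$settings$stratum)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Library-search benchmark across weighting schemes and ppm windows
#'
#' Runs [library_search()] for every combination of scheme and precursor
#' window and summarizes each run with precision at the requested depths,
#' pooled-hit AUC-ROC (scores vs InChIKey-14 truth; `NA` when only one class
#' is present) and the no-match counts at score 0.5.
#'
#' @param bench A `synthetic_benchmark`.
#' @param schemes Character vector of weighting scheme names.
#' @param ppm Numeric vector of precursor windows (parts per million).
#' @param metric Registered similarity metric name.
#' @param table Frequency table for frequency-mode schemes (built from
#'   `bench$reference` when `NULL`).
#' @param tolerance Fragment m/z tolerance in Th.
#' @param ks Depths for precision at K.
#' @return A data frame with one row per (scheme, ppm) and columns
#'   `precision_at_<k>`, `auc_roc`, `no_match`, `no_true_positive_match`.
#' @export
search_benchmark <- function(bench, schemes = c("unweighted", "proposed"),
                             ppm = c(10, 5000), metric = "modified_cosine",
                             table = NULL, tolerance = 0.1,
                             ks = c(1, 5, 10)) {
  if (is.null(table) &&
      any(vapply(schemes,
                 function(s) identical(weight_scheme(s)$mode, "frequency"),
                 logical(1)))) {
    table <- build_frequency_table(bench$reference)
  }
  grid <- expand.grid(scheme = schemes, ppm = ppm,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    res <- library_search(bench$queries, bench$reference,
                          ppm = grid$ppm[g], metric = metric,
                          scheme = grid$scheme[g], table = table,
                          tolerance = tolerance)
    prec <- vapply(ks, function(k) precision_at_k(res, k), numeric(1))
    names(prec) <- paste0("precision_at_", ks)
    lab <- res$hits$is_tp %in% TRUE
    auc <- if (nrow(res$hits) > 0 && length(unique(lab)) == 2) {
      auc_roc(res$hits$score, as.integer(lab))
    } else NA_real_
    nm <- count_no_match_queries(res, 0.5)
    cbind(data.frame(scheme = grid$scheme[g], ppm = grid$ppm[g],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(prec)),
          data.frame(auc_roc = auc, no_match = nm[["no_match"]],
                     no_true_positive_match =
                       nm[["no_true_positive_match"]]))
  })
  do.call(rbind, rows)
}
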