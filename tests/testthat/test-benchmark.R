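test_that("tanimoto coefficient follows inclusion-exclusion", {
  a <- c(1, 1, 1, 0, 0, 0)
  b <- c(1, 1, 0, 1, 0, 0)
  expect_equal(tanimoto(a, b), 2 / 4)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0.0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 0)), "equal length")
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 1.0)
})

test_that("structural labels use a strict threshold by default", {
  tans <- c(0.71, 0.70, 0.69)
  expect_equal(label_pairs(tans, 0.7), c(1L, 0L, 0L))
  expect_equal(label_pairs(tans, 0.7, boundary = "gte"), c(1L, 1L, 0L))
  # sensitivity threshold 0.8 relabels accordingly
  expect_equal(label_pairs(c(0.85, 0.75), 0.8), c(1L, 0L))
})

test_that("optimal cutoff separates a separable 3-point example", {
  res <- optimal_cutoff(c(0.9, 0.8, 0.3), c(1, 0, 0))
  expect_equal(res$fbeta, 1.0)
  expect_true(res$cutoff > 0.8 && res$cutoff <= 0.9)
  ct <- contingency(c(0.9, 0.8, 0.3), c(1, 0, 0), 0.85)
  expect_equal(unname(ct), c(1L, 0L, 0L, 2L))
})

test_that("optimal cutoff returns the lowest maximizer on separable data", {
  scores <- c(0.2, 0.3, 0.7, 0.9)
  labels <- c(0, 0, 1, 1)
  res <- optimal_cutoff(scores, labels)
  expect_equal(res$fbeta, 1.0)
  # lowest candidate cutoff with F1 = 1 is the grid point just above 0.3
  expect_equal(res$cutoff, 0.31)
  expect_error(optimal_cutoff(scores, c(1, 1, 1, 1)), "both classes")
})

test_that("optimal cutoff and contingency match a brute-force scan", {
  set.seed(91)
  for (beta in c(1, 2)) {
    scores <- round(runif(1000), 3)
    labels <- as.integer(runif(1000) < plogis(6 * scores - 3))
    if (length(unique(labels)) < 2) next
    fast <- optimal_cutoff(scores, labels, beta = beta)
    slow <- oracle_best_cutoff(scores, labels, beta = beta)
    expect_equal(fast$cutoff, unname(slow["cutoff"]))
    expect_equal(fast$fbeta, unname(slow["fbeta"]))
    ct <- contingency(scores, labels, fast$cutoff)
    expect_equal(sum(ct), 1000L)
    expect_equal(unname(ct["tp"]),
                 sum(scores >= fast$cutoff & labels == 1))
  }
})

test_that("degenerate cutoffs behave as documented", {
  scores <- c(0.1, 0.6, 0.9)
  labels <- c(0, 1, 1)
  ct0 <- contingency(scores, labels, 0)
  expect_equal(unname(ct0["tn"] + ct0["fn"]), 0L)
  ct1 <- contingency(scores, labels, 1)
  expect_equal(unname(ct1["tp"] + ct1["fp"]), 0L)
})

test_that("KL divergence has its closed forms and properties", {
  set.seed(92)
  x <- runif(500)
  expect_equal(kl_to_reference(x, x), 0.0)
  # P concentrated in bin 1 vs Q uniform over both bins of a 2-bin histogram
  p_sample <- rep(0.25, 400)
  q_sample <- c(rep(0.25, 200), rep(0.75, 200))
  expect_equal(kl_to_reference(p_sample, q_sample, n_bins = 2), log(2),
               tolerance = 1e-6)
  # asymmetry witness and non-negativity
  kl_pq <- kl_to_reference(p_sample, q_sample, n_bins = 4)
  kl_qp <- kl_to_reference(q_sample, p_sample, n_bins = 4)
  expect_false(isTRUE(all.equal(kl_pq, kl_qp)))
  expect_gte(kl_pq, 0)
  expect_gte(kl_qp, 0)
  expect_error(kl_to_reference(x, x, n_bins = 1), "at least 2")
})

test_that("rank-based AUC matches the O(n^2) concordance oracle", {
  # boundary cases
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_roc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_roc(c(0.1, 0.2), c(1, 1)), "both classes")
  # 6-point fixture with ties
  s6 <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.3)
  l6 <- c(1, 1, 0, 0, 1, 0)
  expect_equal(auc_roc(s6, l6), oracle_auc(s6, l6))
  # 1000-point random fixture
  set.seed(93)
  scores <- round(runif(1000), 2)
  labels <- as.integer(runif(1000) < scores)
  expect_equal(auc_roc(scores, labels), oracle_auc(scores, labels))
})

test_that("precision at K counts truncated top lists and empty queries", {
  hits <- data.frame(
    query_id = c(rep("q1", 5), rep("q2", 2)),
    rank = c(1:5, 1:2),
    library_id = paste0("L", 1:7),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.95, 0.2),
    delta_ppm = 0,
    is_tp = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  res <- structure(list(hits = hits, query_ids = c("q1", "q2", "q3"),
                        params = list()), class = "search_results")
  # q1: 2/5, q2: 2/2 (k truncates to the returned list), q3: no hits -> 0
  expect_equal(precision_at_k(res, 5), mean(c(0.4, 1, 0)))
  expect_equal(precision_at_k(res, 1), mean(c(1, 1, 0)))
  # k beyond every list length equals full-list precision
  expect_equal(precision_at_k(res, 50), precision_at_k(res, 5))
})

test_that("no-match counting distinguishes any-match from true-positive", {
  hits <- data.frame(
    query_id = c("q1", "q2", "q2"),
    rank = c(1, 1, 2),
    library_id = c("L1", "L2", "L3"),
    score = c(0.4, 0.8, 0.6),
    delta_ppm = 0,
    is_tp = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  res <- structure(list(hits = hits, query_ids = c("q1", "q2", "q3"),
                        params = list()), class = "search_results")
  counts <- count_no_match_queries(res, 0.5)
  # q1 best 0.4 and q3 empty have no match above 0.5; q2 has one, and its
  # true positive scores 0.6
  expect_equal(unname(counts["no_match"]), 2L)
  expect_equal(unname(counts["no_true_positive_match"]), 2L)
  at0 <- count_no_match_queries(res, 0)
  expect_equal(unname(at0["no_match"]), 1L)  # only the empty query
})

test_that("dominant peak profiling flags the failure regime", {
  dom <- dominant_peak_profile(spec(c(100, 150, 200), c(8, 1, 1),
                                    prec = 300))
  expect_equal(dom$max_share, 0.8)
  expect_false(dom$advise_weighting)
  unif <- dominant_peak_profile(spec(50 + (1:10) * 10, rep(1, 10),
                                     prec = 300))
  expect_equal(unif$max_share, 0.1)
  expect_true(unif$advise_weighting)
  single <- dominant_peak_profile(spec(100, 3, prec = 300))
  expect_equal(single$max_share, 1.0)
  expect_equal(single$n_peaks, 1L)
  expect_false(single$advise_weighting)
})

test_that("library search windows, ranking and truth flags are correct", {
  lib <- spectrum_library(list(
    spec(c(100, 150, 200), c(1, 2, 3), prec = 500.000, id = "ref1",
         key = "AAAAAAAAAAAAAA-X"),
    spec(c(100, 150, 210), c(1, 2, 3), prec = 500.004, id = "ref2",
         key = "BBBBBBBBBBBBBB-X"),
    spec(c(100, 150, 220), c(1, 2, 3), prec = 501.5, id = "ref3",
         key = "AAAAAAAAAAAAAA-X")
  ))
  q <- spectrum_library(list(
    spec(c(100, 150, 200), c(1, 2, 3), prec = 500.000, id = "q1",
         key = "aaaaaaaaaaaaaa-Y")
  ))
  # 10 ppm window at 500 Th is +/- 0.005: ref1 and ref2 only
  res <- library_search(q, lib, ppm = 10, metric = "modified_cosine")
  expect_setequal(res$hits$library_id, c("ref1", "ref2"))
  expect_equal(res$hits$library_id[res$hits$rank == 1], "ref1")
  expect_equal(res$hits$score[res$hits$rank == 1], 1.0)
  expect_true(res$hits$is_tp[res$hits$rank == 1])  # case-insensitive key
  expect_false(res$hits$is_tp[res$hits$rank == 2])
  # 5000 ppm window is a superset
  res5k <- library_search(q, lib, ppm = 5000, metric = "modified_cosine")
  expect_true(all(res$hits$library_id %in% res5k$hits$library_id))
  expect_setequal(res5k$hits$library_id, c("ref1", "ref2", "ref3"))
})
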