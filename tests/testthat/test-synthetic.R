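cfg_small <- generator_config(seed = 9, n_templates = 12)

test_that("template generation is deterministic and respects constraints", {
  t1 <- make_templates(cfg_small)
  t2 <- make_templates(cfg_small)
  expect_identical(t1, t2)
  for (t in t1) {
    expect_true(all(diff(t$fragment_mz) > 2 * cfg_small$tolerance))
    expect_true(all(t$fragment_mz >= 50))
    expect_true(all(t$fragment_mz <= t$precursor_mz - 2))
    expect_equal(max(t$base_intensity), 1)
    expect_equal(nchar(t$inchikey14), 14L)
    expect_equal(sum(t$fingerprint), length(unique(t$fragment_bit)))
  }
  # changing the seed changes the templates
  expect_false(identical(
    t1[[1]]$fragment_mz,
    make_templates(generator_config(seed = 10, n_templates = 12))[[1]]$fragment_mz))
})

test_that("template fingerprint Tanimoto matches fragment-set Jaccard", {
  cfg <- generator_config(seed = 14, n_templates = 30)
  tm <- make_templates(cfg)
  for (i in 1:15) {
    a <- tm[[i]]; b <- tm[[31 - i]]
    # fragment identity is the 0.1-Th bin the fingerprint bits encode
    ka <- round(a$fragment_mz * 10); kb <- round(b$fragment_mz * 10)
    jac <- length(intersect(ka, kb)) / length(union(ka, kb))
    expect_lt(abs(tanimoto(a$fingerprint, b$fingerprint) - jac), 0.05)
  }
})

test_that("noise-free replicates reproduce the template exactly", {
  cfg0 <- generator_config(seed = 5, n_templates = 3, mz_jitter_sd = 0,
                           intensity_noise_sd = 0, dropout_prob = 0,
                           dominant_peak_prob = 0)
  tm <- make_templates(cfg0)
  s <- spectrum_from_template(tm[[1]], cfg0, 1)
  expect_equal(s$mz, tm[[1]]$fragment_mz)
  expect_equal(s$intensity, tm[[1]]$base_intensity)
  expect_equal(s$precursor_mz, tm[[1]]$precursor_mz)
  expect_equal(s$inchikey, tm[[1]]$inchikey14)
})

test_that("replicates are deterministic per seed and similar to each other", {
  tm <- make_templates(cfg_small)
  r1 <- spectrum_from_template(tm[[2]], cfg_small, "a")
  r1b <- spectrum_from_template(tm[[2]], cfg_small, "a")
  expect_identical(r1$mz, r1b$mz)
  expect_identical(r1$intensity, r1b$intensity)
  # replicate pairs of one template score high under modified cosine:
  # a deterministic sweep at the default noise model
  scores <- vapply(1:60, function(i) {
    t <- tm[[(i %% 12) + 1]]
    modified_cosine(spectrum_from_template(t, cfg_small, paste0("x", i)),
                    spectrum_from_template(t, cfg_small, paste0("y", i)))
  }, numeric(1))
  expect_gte(mean(scores > 0.8), 0.95)
  expect_gt(median(scores), 0.9)
})

test_that("forced dominance boosts the configured share", {
  cfg1 <- generator_config(seed = 8, n_templates = 4,
                           dominant_peak_prob = 1)
  for (t in make_templates(cfg1)) {
    prof <- dominant_peak_profile(spectrum_from_template(t, cfg1, 1))
    expect_gte(prof$max_share, cfg1$dominant_share - 1e-9)
  }
  # dominance is a template-level coin: replicates agree
  cfg2 <- generator_config(seed = 8, n_templates = 20,
                           dominant_peak_prob = 0.5)
  for (t in make_templates(cfg2)[1:10]) {
    d1 <- attr(spectrum_from_template(t, cfg2, 1), "dominant")
    d2 <- attr(spectrum_from_template(t, cfg2, 2), "dominant")
    expect_identical(d1, d2)
  }
})

test_that("analogs retain, shift and recalibrate as constructed", {
  cfg <- generator_config(seed = 16, n_templates = 6)
  tm <- make_templates(cfg)
  t <- tm[[1]]
  # overlap 1: identical fragments, shifted precursor, Tanimoto 1
  a1 <- make_analog(t, 1, 18.0106, seed = 3, config = cfg)
  expect_equal(a1$fragment_mz, t$fragment_mz)
  expect_equal(a1$precursor_mz, t$precursor_mz + 18.0106)
  expect_equal(tanimoto(t$fingerprint, a1$fingerprint), 1.0)
  expect_equal(a1$inchikey14, t$inchikey14)
  # overlap 0 on a noise-free pair: modified cosine stays 1, cosine drops
  cfg0 <- generator_config(seed = 16, n_templates = 1, mz_jitter_sd = 0,
                           intensity_noise_sd = 0, dropout_prob = 0,
                           dominant_peak_prob = 0)
  t0 <- make_templates(cfg0)[[1]]
  a0 <- make_analog(t0, 0, 18.0106, seed = 3, config = cfg0)
  s_t <- spectrum_from_template(t0, cfg0, 1)
  s_a <- spectrum(a0$fragment_mz, a0$base_intensity,
                  precursor_mz = a0$precursor_mz, id = "analog0")
  expect_equal(modified_cosine(s_t, s_a), 1.0)
  expect_lt(cosine_score(s_t, s_a), 0.2)
  expect_false(a0$inchikey14 == t0$inchikey14)
})

test_that("analog Tanimoto is calibrated to the overlap fraction", {
  cfg <- generator_config(seed = 17, n_templates = 25)
  tm <- make_templates(cfg)
  set.seed(18)
  ov <- runif(400)
  tt <- vapply(seq_along(ov), function(i) {
    t <- tm[[(i %% 25) + 1]]
    an <- make_analog(t, ov[i], 18.0106, seed = i, config = cfg)
    tanimoto(t$fingerprint, an$fingerprint)
  }, numeric(1))
  expect_lt(mean(abs(tt - ov)), 0.08)
  expect_gt(cor(tt, ov), 0.95)
  # near overlap 0.5 the coefficient concentrates near 0.5
  mid <- abs(ov - 0.5) < 0.1
  expect_lt(abs(mean(tt[mid]) - 0.5), 0.05)
})

test_that("fragment-set Jaccard and fingerprint Tanimoto track each other
          across analog pairs", {
  cfg <- generator_config(seed = 19, n_templates = 25)
  tm <- make_templates(cfg)
  set.seed(20)
  ov <- runif(500)
  jac <- numeric(500); tan <- numeric(500)
  for (i in 1:500) {
    t <- tm[[(i %% 25) + 1]]
    an <- make_analog(t, ov[i], 18.0106, seed = i, config = cfg)
    jac[i] <- length(intersect(t$fragment_mz, an$fragment_mz)) /
      length(union(t$fragment_mz, an$fragment_mz))
    tan[i] <- tanimoto(t$fingerprint, an$fingerprint)
  }
  expect_gte(cor(jac, tan), 0.95)
})

test_that("the benchmark set is deterministic with partitioning strata", {
  cfg <- generator_config(seed = 23, n_templates = 20)
  b1 <- make_benchmark(cfg, n_pairs = 40, n_queries = 15)
  b2 <- make_benchmark(cfg, n_pairs = 40, n_queries = 15)
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(lapply(b1$pair_spectra$spectra, `[[`, "intensity"),
                   lapply(b2$pair_spectra$spectra, `[[`, "intensity"))
  expect_identical(b1$fingerprints, b2$fingerprints)
  # strata partition the pairs
  expect_true(all(b1$pairs$stratum %in% c("dominant", "no_dominant")))
  expect_equal(sum(b1$pairs$stratum == "dominant") +
                 sum(b1$pairs$stratum == "no_dominant"), 40L)
  expect_equal(nrow(b1$pairs), 40L)
  expect_equal(length(b1$pair_spectra), 80L)
  expect_equal(length(b1$reference), 20L)
  expect_equal(length(b1$queries), 15L)
  expect_true(all(b1$pairs$tanimoto >= 0 & b1$pairs$tanimoto <= 1))
})

test_that("every query precursor sits inside its reference 10 ppm window", {
  cfg <- generator_config(seed = 24, n_templates = 15)
  b <- make_benchmark(cfg, n_pairs = 10, n_queries = 30)
  ref_prec <- vapply(b$reference$spectra, `[[`, numeric(1), "precursor_mz")
  ref_key <- vapply(b$reference$spectra, `[[`, character(1), "inchikey")
  for (q in b$queries$spectra) {
    matching <- ref_prec[ref_key == q$inchikey]
    expect_true(any(abs(q$precursor_mz - matching) <=
                      10 * q$precursor_mz / 1e6))
  }
})

test_that("benchmark MGF/TSV outputs are byte-identical across runs", {
  cfg <- generator_config(seed = 7, n_templates = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    b <- make_benchmark(cfg, n_pairs = 10, n_queries = 5)
    write_mgf(b$reference, file.path(d, "reference.mgf"))
    write.table(b$pairs, file.path(d, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  expect_identical(readLines(file.path(d1, "reference.mgf")),
                   readLines(file.path(d2, "reference.mgf")))
  expect_identical(readLines(file.path(d1, "pairs.tsv")),
                   readLines(file.path(d2, "pairs.tsv")))
})
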