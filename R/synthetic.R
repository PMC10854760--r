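# Seeded synthetic spectra: molecule templates, measurement replicates,
# constant-shift analogs, and the two benchmark layouts (alignment pairs and
# library search). Everything is deterministic given the config seed; each
# template and replicate draws from its own derived seed, so adding templates
# never perturbs existing ones.

#' Configuration for the synthetic-spectrum generator
#'
#' Defaults describe a generic small-molecule MS/MS library: 8-40 fragments
#' per molecule on an integer-plus-offset m/z grid in \[50, 290\] Th,
#' precursors in \[300, 900\] Th, long-tailed log-normal intensities
#' (max-normalized), mild measurement noise, and analogs sharing 50-100% of
#' their fragments with the remainder carried across a constant neutral-loss
#' shift.
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param n_templates Number of molecule templates.
#' @param peaks_per_template Length-2 range of fragments per template.
#' @param mz_jitter_sd Per-replicate fragment m/z jitter SD (Th); kept below
#'   half the fragment tolerance so true matches survive matching.
#' @param intensity_noise_sd SD of the multiplicative log-normal intensity
#'   noise applied per replicate.
#' @param dropout_prob Probability that a replicate loses a given fragment.
#' @param dominant_peak_prob Probability that a replicate's strongest peak is
#'   boosted into a dominant peak (and, in [make_benchmark()], the fraction
#'   of pairs assigned to the dominant-peak stratum).
#' @param dominant_share Total-intensity share given to a boosted dominant
#'   peak.
#' @param analog_overlap Length-2 range of the fragment-overlap fraction used
#'   when deriving analogs.
#' @param analog_mass_shift Default constant neutral-loss shift (Th) applied
#'   to non-retained analog fragments (water loss by default).
#' @param fingerprint_bits Fingerprint length in bits.
#' @param precursor_range,fragment_range m/z ranges (Th) for precursors and
#'   fragments.
#' @param tolerance Fragment tolerance (Th) the spectra are destined for;
#'   drives the template peak-separation constraint.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_templates = 200L,
                             peaks_per_template = c(8L, 40L),
                             mz_jitter_sd = 0.01,
                             intensity_noise_sd = 0.3,
                             dropout_prob = 0.1,
                             dominant_peak_prob = 0.25,
                             dominant_share = 0.8,
                             analog_overlap = c(0.5, 1),
                             analog_mass_shift = 18.0106,
                             fingerprint_bits = 8192L,
                             precursor_range = c(300, 900),
                             fragment_range = c(50, 290),
                             tolerance = 0.1) {
  probs <- c(dropout_prob, dominant_peak_prob, dominant_share)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities and shares must lie in [0, 1]", call. = FALSE)
  }
  if (any(analog_overlap < 0) || any(analog_overlap > 1)) {
    stop("`analog_overlap` must lie in [0, 1]", call. = FALSE)
  }
  if (mz_jitter_sd >= tolerance / 2) {
    stop("`mz_jitter_sd` must be below tolerance / 2 so that true matches ",
         "survive peak matching", call. = FALSE)
  }
  stopifnot(length(peaks_per_template) == 2, peaks_per_template[1] >= 1,
            diff(peaks_per_template) >= 0, n_templates >= 1)
  structure(
    list(seed = as.integer(seed), n_templates = as.integer(n_templates),
         peaks_per_template = as.integer(peaks_per_template),
         mz_jitter_sd = mz_jitter_sd,
         intensity_noise_sd = intensity_noise_sd,
         dropout_prob = dropout_prob,
         dominant_peak_prob = dominant_peak_prob,
         dominant_share = dominant_share,
         analog_overlap = analog_overlap,
         analog_mass_shift = analog_mass_shift,
         fingerprint_bits = as.integer(fingerprint_bits),
         precursor_range = precursor_range,
         fragment_range = fragment_range,
         tolerance = tolerance),
    class = "generator_config"
  )
}

# Stable 31-bit seed derived from (seed, id-string): a small multiplicative
# string hash, so per-template streams are independent of template order.
derive_seed <- function(seed, id) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Fingerprint bit for a fragment m/z: its 0.1-Th integer key folded onto the
# fingerprint length. One bit per distinct fragment mass, so for templates
# the Tanimoto coefficient of two fingerprints tracks the Jaccard overlap of
# the fragment sets (up to rare fold collisions). Analogs manipulate the
# per-fragment bits directly (see make_analog).
bit_for_mz <- function(mz, bits) {
  (as.integer(round(mz * 10)) %% bits) + 1L
}

fingerprint_from_bits <- function(bit_idx, bits) {
  fp <- logical(bits)
  fp[bit_idx] <- TRUE
  fp
}

random_inchikey14 <- function() {
  paste(sample(LETTERS, 14, replace = TRUE), collapse = "")
}

#' Generate molecule templates
#'
#' Each template stands in for a compound: a precursor m/z, a set of fragment
#' m/z values on an integer-plus-random-offset grid (pairwise separation well
#' above twice the fragment tolerance), max-normalized log-normal base
#' intensities, a synthetic 14-character InChIKey block, and a fingerprint
#' whose bits derive from the fragment masses so that fingerprint Tanimoto
#' tracks fragment-set Jaccard overlap.
#'
#' @param config A [generator_config()].
#' @return List of `molecule_template` objects, deterministic given the seed.
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  lapply(seq_len(config$n_templates), function(i) {
    template_id <- sprintf("T%03d", i)
    with_seed(derive_seed(config$seed, template_id), {
      k <- sample(seq(config$peaks_per_template[1],
                      config$peaks_per_template[2]), 1)
      lo <- ceiling(config$fragment_range[1])
      hi <- floor(config$fragment_range[2])
      if (hi - lo + 1 < k) {
        stop("fragment range too narrow for ", k,
             " fragments at integer spacing", call. = FALSE)
      }
      offset <- round(stats::runif(1, 0.05, 0.95), 3)
      frag <- sort(sample(seq(lo, hi), k)) + offset
      precursor <- round(stats::runif(1, config$precursor_range[1],
                                      config$precursor_range[2]), 4)
      base <- stats::rlnorm(k, meanlog = 0, sdlog = 1)
      base <- base / max(base)
      bit_idx <- bit_for_mz(frag, config$fingerprint_bits)
      structure(
        list(template_id = template_id,
             precursor_mz = precursor,
             fragment_mz = frag,
             base_intensity = base,
             fragment_bit = bit_idx,
             fingerprint = fingerprint_from_bits(bit_idx,
                                                 config$fingerprint_bits),
             inchikey14 = random_inchikey14()),
        class = "molecule_template"
      )
    })
  })
}

#' @export
print.molecule_template <- function(x, ...) {
  cat(sprintf("<molecule_template> %s: %d fragments, precursor m/z %.4f, key %s\n",
              x$template_id, length(x$fragment_mz), x$precursor_mz,
              x$inchikey14))
  invisible(x)
}

#' Simulate a measured spectrum from a template
#'
#' Emulates a measurement replicate. Fragment dropout models a detection
#' limit: fragment `i` is lost with probability
#' `dropout_prob * (1 - base_intensity_i)`, so weak peaks disappear at up to
#' the configured rate while the base peak always survives (replicates of
#' one template therefore stay recognizably similar). Surviving m/z values
#' receive Gaussian jitter and intensities multiplicative log-normal noise.
#' Dominance is a property of the molecule, not the measurement: whether a
#' template yields dominant-peak spectra is decided by a coin seeded from
#' the template identity (probability `dominant_peak_prob`), shared by all
#' of its replicates; a dominant replicate's strongest template peak (or the
#' fragment nearest `dominant_mz`, which is then exempt from dropout) is
#' boosted after noise to carry exactly `dominant_share` of the total
#' intensity. If every fragment drops out, dropout is disabled for the
#' replicate and the result flagged via the `"dropout_rescued"` attribute.
#'
#' @param template A `molecule_template`.
#' @param config A [generator_config()].
#' @param replicate_seed Integer or string distinguishing replicates of one
#'   template.
#' @param dominant `NULL` to use the template-level dominance coin, or
#'   `TRUE`/`FALSE` to force it.
#' @param dominant_mz Fragment m/z (template scale) to boost when dominant;
#'   defaults to the strongest template peak.
#' @return An `ms_spectrum` whose `inchikey` is the template's key block.
#' @export
spectrum_from_template <- function(template, config, replicate_seed = 1L,
                                   dominant = NULL, dominant_mz = NULL) {
  stopifnot(inherits(template, "molecule_template"),
            inherits(config, "generator_config"))
  if (is.null(dominant)) {
    dominant <- with_seed(
      derive_seed(config$seed, paste0(template$template_id, "+dominant")),
      stats::runif(1) < config$dominant_peak_prob)
  }
  with_seed(derive_seed(config$seed,
                        paste0(template$template_id, "#", replicate_seed)), {
    k <- length(template$fragment_mz)
    rel <- template$base_intensity / max(template$base_intensity)
    keep <- stats::runif(k) > config$dropout_prob * (1 - rel)
    target_k <- if (isTRUE(dominant)) {
      if (!is.null(dominant_mz)) {
        which.min(abs(template$fragment_mz - dominant_mz))
      } else which.max(template$base_intensity)
    } else NA_integer_
    if (!is.na(target_k)) keep[target_k] <- TRUE
    rescued <- FALSE
    if (!any(keep)) {
      keep <- rep(TRUE, k)
      rescued <- TRUE
    }
    mz <- template$fragment_mz[keep] +
      stats::rnorm(sum(keep), 0, config$mz_jitter_sd)
    int <- template$base_intensity[keep] *
      exp(stats::rnorm(sum(keep), 0, config$intensity_noise_sd))
    if (isTRUE(dominant) && length(int) > 1L) {
      target <- which(which(keep) == target_k)
      share <- config$dominant_share
      int[target] <- share / (1 - share) * sum(int[-target])
    }
    out <- spectrum(mz, int, precursor_mz = template$precursor_mz,
                    id = sprintf("%s.r%s", template$template_id,
                                 replicate_seed),
                    inchikey = template$inchikey14)
    attr(out, "dropout_rescued") <- rescued
    attr(out, "dominant") <- isTRUE(dominant)
    out
  })
}

#' Derive a structural analog of a template
#'
#' Retains `ceiling(overlap * n)` randomly chosen fragments and shifts the
#' remainder -- and the precursor -- by a constant `mass_shift`, emulating a
#' shared substructure plus a single mass modification (the signal
#' precursor-shifted peak matching exploits). The fingerprint is rebuilt
#' from the new fragment set: retained fragments keep their substructure
#' bit, while a fragment carried across the modification keeps its bit with
#' probability `overlap / (1 + overlap)` and otherwise contributes a fresh
#' bit derived from its shifted mass. That retention rate is calibrated so
#' the expected parent-analog Tanimoto coefficient equals `overlap`. Shifted
#' fragments landing within twice the tolerance of a retained fragment are
#' dropped (counted in the `"dropped_fragments"` attribute) to preserve the
#' peak-separation invariant.
#'
#' @param template Parent `molecule_template`.
#' @param overlap Fraction of fragments retained, in \[0, 1\].
#' @param mass_shift Constant shift in Th.
#' @param seed Integer seed selecting which fragments are retained.
#' @param config A [generator_config()] (fingerprint length and tolerance).
#' @return A new `molecule_template`.
#' @export
make_analog <- function(template, overlap, mass_shift, seed = 1L,
                        config = generator_config()) {
  stopifnot(inherits(template, "molecule_template"),
            overlap >= 0, overlap <= 1)
  with_seed(derive_seed(seed, paste0(template$template_id, ">analog")), {
    k <- length(template$fragment_mz)
    n_keep <- ceiling(overlap * k)
    # retention is intensity-biased: the shared core scaffold produces the
    # major fragments, so strong peaks are preferentially carried over and
    # the modification mostly relocates minor peaks
    keep_idx <- sort(sample(seq_len(k), n_keep,
                            prob = template$base_intensity))
    shift_idx <- setdiff(seq_len(k), keep_idx)
    kept_mz <- template$fragment_mz[keep_idx]
    shifted_mz <- template$fragment_mz[shift_idx] + mass_shift
    # preserve pairwise separation: drop shifted fragments colliding with
    # retained ones
    ok <- if (length(kept_mz)) {
      vapply(shifted_mz,
             function(m) min(abs(m - kept_mz)) > 2 * config$tolerance,
             logical(1))
    } else rep(TRUE, length(shifted_mz))
    frag <- c(kept_mz, shifted_mz[ok])
    base <- c(template$base_intensity[keep_idx],
              template$base_intensity[shift_idx][ok])
    # substructure bits: retained fragments keep theirs; shifted fragments
    # keep theirs with prob overlap/(1+overlap) (E[Tanimoto] = overlap)
    shifted_bits <- template$fragment_bit[shift_idx][ok]
    survives <- stats::runif(length(shifted_bits)) <
      overlap / (1 + overlap)
    new_bits <- bit_for_mz(shifted_mz[ok], config$fingerprint_bits)
    shifted_bits[!survives] <- new_bits[!survives]
    bit_idx <- c(template$fragment_bit[keep_idx], shifted_bits)
    o <- order(frag)
    out <- structure(
      list(template_id = paste0(template$template_id, "a"),
           precursor_mz = template$precursor_mz + mass_shift,
           fragment_mz = frag[o],
           base_intensity = base[o],
           fragment_bit = bit_idx[o],
           fingerprint = fingerprint_from_bits(bit_idx,
                                               config$fingerprint_bits),
           inchikey14 = if (overlap >= 1) template$inchikey14
                        else random_inchikey14()),
      class = "molecule_template"
    )
    attr(out, "dropped_fragments") <- sum(!ok)
    out
  })
}

# Clean (noise-free) spectrum of a template: the reference-library entry.
template_spectrum <- function(template, suffix = "ref") {
  spectrum(template$fragment_mz, template$base_intensity,
           precursor_mz = template$precursor_mz,
           id = sprintf("%s.%s", template$template_id, suffix),
           inchikey = template$inchikey14)
}

# Neutral-loss-like constant shifts (Th) drawn for benchmark analogs: water,
# CO/ethylene, ketene, formic acid, hexose.
benchmark_shift_pool <- c(18.0106, 28.0313, 42.0106, 46.0055, 162.0528)

#' Generate the full synthetic benchmark
#'
#' Builds, deterministically from the config seed: (a) a labeled spectrum
#' pair set for the alignment benchmark, stratified by dominant-peak status
#' and carrying fragment-overlap metadata; (b) a reference library with one
#' clean spectrum per template; (c) a query library of noisy measurement
#' replicates for library search; (d) a fingerprint table.
#'
#' Related pairs put a template against a two-step analog (an analog of an
#' analog, with independent overlaps and neutral-loss shifts), which keeps
#' the pair's modified-cosine matching away from saturation: fragments kept
#' or shifted in both steps still match (directly or via the precursor
#' difference), while fragments kept in one step and shifted in the other do
#' not. Unrelated pairs put two different templates together. Pairs in the
#' dominant stratum boost a fragment shared by both spectra into a dominant
#' peak, reproducing the regime where weighting lowers the score of
#' structurally similar pairs.
#'
#' @param config A [generator_config()].
#' @param n_pairs Number of alignment benchmark pairs.
#' @param n_queries Number of library-search query spectra.
#' @param unrelated_frac Fraction of pairs drawn from two unrelated
#'   templates.
#' @return An object of class `synthetic_benchmark`: list with `pairs` (data
#'   frame `id_a`, `id_b`, `tanimoto`, `overlap`, `dominant`, `stratum`,
#'   `kind`), `pair_spectra`, `reference`, `queries` (all `ms_library`) and
#'   `fingerprints` (data frame `id`, `inchikey14`, `bits`).
#' @export
make_benchmark <- function(config = generator_config(), n_pairs = 2000L,
                           n_queries = 500L, unrelated_frac = 0.3) {
  stopifnot(inherits(config, "generator_config"))
  templates <- make_templates(config)
  reference <- spectrum_library(lapply(templates, template_spectrum),
                                source = "synthetic-reference")
  queries <- with_seed(derive_seed(config$seed, "queries"), {
    idx <- sample(length(templates), n_queries, replace = TRUE)
    reps <- lapply(seq_len(n_queries), function(i) {
      s <- spectrum_from_template(templates[[idx[i]]], config,
                                  replicate_seed = paste0("q", i))
      s$id <- sprintf("Q%04d.%s", i, s$id)
      s
    })
    spectrum_library(reps, source = "synthetic-queries")
  })
  fp_rows <- lapply(templates, function(t) {
    data.frame(id = t$template_id, inchikey14 = t$inchikey14,
               bits = paste(as.integer(t$fingerprint), collapse = ""),
               stringsAsFactors = FALSE)
  })
  pair_rows <- vector("list", n_pairs)
  pair_spectra <- vector("list", 2L * n_pairs)
  with_seed(derive_seed(config$seed, "pairs"), {
    for (i in seq_len(n_pairs)) {
      pid <- sprintf("P%05d", i)
      dominant <- stats::runif(1) < config$dominant_peak_prob
      unrelated <- stats::runif(1) < unrelated_frac
      if (unrelated) {
        ti <- sample(length(templates), 2)
        t_a <- templates[[ti[1]]]
        t_b <- templates[[ti[2]]]
        overlap <- NA_real_
        pair_seed <- sample.int(2^30, 1)
        spec_a <- spectrum_from_template(t_a, config,
                                         replicate_seed = paste0(pid, "a"),
                                         dominant = dominant)
        spec_b <- spectrum_from_template(t_b, config,
                                         replicate_seed = paste0(pid, "b"),
                                         dominant = dominant)
        kind <- "unrelated"
      } else {
        t_a <- templates[[sample(length(templates), 1)]]
        q1 <- stats::runif(1, config$analog_overlap[1],
                           config$analog_overlap[2])
        q2 <- stats::runif(1, config$analog_overlap[1],
                           config$analog_overlap[2])
        shifts <- sample(benchmark_shift_pool, 2, replace = TRUE)
        pair_seed <- sample.int(2^30, 1)
        mid <- make_analog(t_a, q1, shifts[1], seed = pair_seed,
                           config = config)
        t_b <- make_analog(mid, q2, shifts[2], seed = pair_seed,
                           config = config)
        overlap <- q1 * q2
        shared <- intersect(t_a$fragment_mz, t_b$fragment_mz)
        dom_mz <- if (length(shared)) {
          shared[which.max(t_a$base_intensity[match(shared,
                                                    t_a$fragment_mz)])]
        } else NULL
        spec_a <- spectrum_from_template(t_a, config,
                                         replicate_seed = paste0(pid, "a"),
                                         dominant = dominant,
                                         dominant_mz = dom_mz)
        spec_b <- spectrum_from_template(t_b, config,
                                         replicate_seed = paste0(pid, "b"),
                                         dominant = dominant,
                                         dominant_mz = dom_mz)
        kind <- "analog"
        fp_rows[[length(fp_rows) + 1L]] <- data.frame(
          id = paste0(pid, ".", t_b$template_id),
          inchikey14 = t_b$inchikey14,
          bits = paste(as.integer(t_b$fingerprint), collapse = ""),
          stringsAsFactors = FALSE)
      }
      spec_a$id <- paste0(pid, ".a")
      spec_b$id <- paste0(pid, ".b")
      pair_spectra[[2L * i - 1L]] <- spec_a
      pair_spectra[[2L * i]] <- spec_b
      pair_rows[[i]] <- data.frame(
        id_a = spec_a$id, id_b = spec_b$id,
        tanimoto = tanimoto(t_a$fingerprint, t_b$fingerprint),
        overlap = overlap,
        dominant = dominant,
        stratum = if (dominant) "dominant" else "no_dominant",
        kind = kind,
        stringsAsFactors = FALSE)
    }
  })
  structure(
    list(pairs = do.call(rbind, pair_rows),
         pair_spectra = spectrum_library(pair_spectra,
                                         source = "synthetic-pairs"),
         reference = reference,
         queries = queries,
         fingerprints = do.call(rbind, fp_rows),
         config = config),
    class = "synthetic_benchmark"
  )
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(
    "<synthetic_benchmark> %d pairs (%d dominant), %d reference, %d queries\n",
    nrow(x$pairs), sum(x$pairs$dominant), length(x$reference),
    length(x$queries)))
  invisible(x)
}
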