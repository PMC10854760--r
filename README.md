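# specweight

Intensity weighting and m/z-frequency weighting for MS/MS spectral
similarity.

## What this is for

Untargeted metabolomics identifies compounds by comparing tandem mass
spectra (MS/MS) against spectral libraries — either looking for a
near-identical library match within a narrow precursor window (library
search) or for structurally related compounds across wide mass differences
(spectral alignment, the basis of molecular networking). Cosine-style
similarity scores sum products of matched peak intensities, so a handful
of strong fragments dominates the score while the many weak fragments that
often carry the structural information barely contribute.

`specweight` implements weighting-based preprocessing that counteracts
this, and the evaluation machinery to measure whether it helps:

* **Classic power weighting** `w = I^n · (m/z)^m` with the published
  parameterizations (Sokolow `n=0.5, m=0.5`; Stein–Scott `n=0.6, m=3`;
  Horai `n=0.5, m=2`; Kim `n=0.53, m=1.3`; intensity-only `n=0.5, m=0`).
* **Frequency-aware weighting** (`proposed`):
  `w = (I / I_max)^0.25 · f(m/z)^0.25`, where `f` is the relative
  occurrence frequency of the peak's 0.1-Th m/z bin across a reference
  library (the fraction of spectra showing a peak there). Low peaks are
  amplified by the fourth root; common fragment masses are up-weighted.
* **Entropy-conditional weighting**: intensities of spectra with spectral
  entropy `S < 3` nats are raised to the power `0.25·(1 + S)`; spectra
  with `S ≥ 3` are untouched.
* **Binarization** (all intensities set to 1).
* **Similarity metrics** over tolerance-based peak matching, direct and
  precursor-shifted: cosine, modified cosine, spectral entropy, fidelity,
  Bhattacharya 1, plus a registry for user metrics.
* **Harnesses**: spectral alignment vs structural (Tanimoto) similarity
  with F-beta-optimal cutoffs, contingency tables and KL divergence; and
  ppm-windowed library search scored by precision@K and AUC-ROC, with
  InChIKey-first-14 ground truth.
* **A seeded synthetic generator** (templates, measurement replicates,
  constant-neutral-loss analogs, fingerprints) so every harness runs with
  no external data.

MGF and MSP spectral libraries are read and written natively; frequency
tables serialize as TSV.

## Worked example

```r
library(specweight)

cfg   <- generator_config(seed = 42, n_templates = 60)
bench <- make_benchmark(cfg, n_pairs = 400, n_queries = 100)

# m/z occurrence frequencies over the clean reference library
freq <- build_frequency_table(bench$reference)
freq
#> <mz_frequency_table> 1052 bins at 0.1 Th over 60 spectra (floor 0.01667, unseen: floor)

# Does weighting help separate structurally similar pairs (Tanimoto > 0.7)?
alignment_benchmark(bench, schemes = c("unweighted", "sokolow", "proposed"))
#> <alignment_report> metric modified_cosine, label: Tanimoto > 0.7
#>      scheme    cutoff     fbeta tp  fp fn  tn        kl
#>  unweighted 0.8017343 0.5358255 86 141  8 165 0.8834257
#>     sokolow 0.8000000 0.5878136 82 103 12 203 0.7747822
#>    proposed 0.7731003 0.6332046 82  83 12 223 0.4603976
```

Each row is one weighting scheme applied before modified cosine: `cutoff`
is the F1-optimal decision threshold on the similarity score, `fbeta` the
F1 it achieves, `tp/fp/fn/tn` the contingency table at that cutoff, and
`kl` the Kullback–Leibler divergence between the score distribution and
the Tanimoto distribution. Here frequency weighting raises F1 from 0.54 to
0.63, cuts false positives from 141 to 83, lowers the optimal cutoff, and
more than halves the KL divergence — the weighted scores resemble the
structural similarities far more closely.

```r
# Library search: noisy query replicates against the clean reference
search_benchmark(bench, schemes = c("unweighted", "proposed"),
                 ppm = c(10, 5000))
#>      scheme  ppm precision_at_1 precision_at_5 precision_at_10 auc_roc no_match no_true_positive_match
#>  unweighted   10              1      1.0000000       1.0000000      NA        2                      2
#>    proposed   10              1      1.0000000       1.0000000      NA        0                      0
#>  unweighted 5000              1      0.8033333       0.8033333       1        2                      2
#>    proposed 5000              1      0.8033333       0.8033333       1        0                      0
```

Every query ranks its true reference first at both windows; widening the
precursor window from 10 to 5,000 ppm admits wrong-molecule candidates and
precision beyond the top hit drops. (AUC is `NA` at 10 ppm because every
candidate inside so narrow a window is a true positive — there is no
negative class to rank against.) `no_match` counts queries without any
hit scoring above 0.5 — weighting rescues the two queries the unweighted
score left unmatched at the 10 ppm window.

A shell entry point wrapping the same functions ships at
`inst/cli/specweight` (subcommands `simulate`, `freq-table`, `weight`,
`pair`, `search`, `benchmark`), e.g.:

```sh
Rscript inst/cli/specweight freq-table --library ref.mgf --out freq.tsv
Rscript inst/cli/specweight pair --metric modified_cosine \
    --scheme proposed --freq-table freq.tsv a.mgf b.mgf
```

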