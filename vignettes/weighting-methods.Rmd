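---
title: "Intensity and m/z-frequency weighting for MS/MS spectral similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity and m/z-frequency weighting for MS/MS spectral similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specweight)
```

## The problem

Annotating a tandem mass spectrum means comparing it against spectra of
known compounds, either to find a near-identical library match (library
search) or to find structurally related compounds that are not exact
matches (spectral alignment, the basis of molecular networking). The
workhorse similarity measures — cosine and its relatives — sum products of
matched peak intensities, so one or two strong fragments can dominate the
score while many weak but structurally informative fragments contribute
almost nothing. Weighting-based preprocessing counteracts this: it
transforms peak intensities before the similarity computation so that low
peaks matter more, and optionally favors fragment masses that recur across
a reference library.

## Weighting transforms

All transforms act on the intensity vector of one spectrum and leave m/z
values untouched; they never move or merge peaks.

**Classic power weighting.** The historical family replaces each intensity
$I$ at mass $m/z$ by

$$ w = I^{\,n} \cdot (m/z)^{\,m}, $$

on raw intensities. The registry carries the published parameterizations:
Sokolow ($n = 0.5, m = 0.5$), Stein–Scott ($n = 0.6, m = 3$), Horai
($n = 0.5, m = 2$), Kim ($n = 0.53, m = 1.3$) and a plain intensity
square-root ($n = 0.5, m = 0$).

**Frequency-aware weighting** (`proposed`). Intensities are first divided
by the spectrum maximum, then compressed and multiplied by the relative
occurrence frequency of the peak's m/z bin in a reference library:

$$ w = \left( \frac{I}{I_{\max}} \right)^{0.25} \cdot f(m/z)^{0.25}. $$

The fourth root strongly amplifies low relative intensities (a peak at
1/16 of the base peak maps to 1/2), and $f$ up-weights common fragment
masses. Max-normalization makes the transform invariant to the absolute
intensity scale.

**Entropy-conditional weighting.** With $S$ the Shannon entropy (nats) of
the sum-normalized spectrum, intensities are left unchanged when
$S \ge 3$ and raised to the power $0.25\,(1 + S)$ otherwise. The exponent
reaches 1 exactly at $S = 3$, so the transform is continuous at the
threshold. All entropies in this package are natural-log entropies; the
threshold 3 is therefore in nats.

**Binarization** sets all positive intensities to 1, keeping only peak
presence.

## The m/z frequency table

`build_frequency_table()` counts, for each 0.1-Th bin (m/z rounded to one
decimal place), the number of reference spectra containing at least one
peak in the bin; a spectrum contributes at most once per bin no matter how
many peaks fall there. The bin key is the integer `round(mz /
resolution)`, so the one-decimal rounding is exact and platform-stable.
Relative frequencies are therefore per-spectrum presence fractions in
$(0, 1]$, invariant under duplicating the library.

A query peak can fall in a bin never seen in the reference library. A
frequency of zero would annihilate the peak under the proposed transform,
which is a stronger statement than the data supports; the default
`unseen_policy = "floor"` instead returns the smallest nonzero frequency
in the table, keeping unseen peaks maximally down-weighted but alive.
`"zero"` and `"one"` are available for sensitivity analysis.

## Peak matching and metrics

`match_peaks()` builds candidate pairs under two rules: *direct*
($|mz_a - mz_b| \le$ tolerance) and, for modified cosine, *shifted*
($|(mz_a - mz_b) - (P_a - P_b)| \le$ tolerance with $P$ the precursor
m/z), which captures fragments carried across a single mass modification.
Candidates are accepted greedily in descending order of intensity product,
with deterministic tie-breaks (smaller residual, then peak indices), each
peak used at most once. Greedy matching mirrors mainstream practice; the
test suite keeps an exhaustive optimal-assignment oracle and verifies that
greedy attains the optimum in well over 95% of random small cases and
never exceeds it.

Five metrics consume the matching: cosine and modified cosine (matched
intensity products over full-spectrum norms, clipped to $[0,1]$), spectral
entropy similarity ($1 - (2 S_{AB} - S_A - S_B)/\ln 4$ on the merged
spectrum whose matched pairs contribute $(p_A + p_B)/2$ and unmatched
peaks enter at half weight), fidelity ($\sum \sqrt{p_a q_b}$ over matched
pairs of sum-normalized spectra) and Bhattacharya 1
($1 - \arccos(F)^2 / (\pi/2)^2$). Probability-based metrics sum-normalize
*after* weighting, so weighted intensities always form a valid
distribution; the arccosine input is clipped to $[0,1]$ to absorb
floating-point overshoot. `register_metric()` adds further matched-peak
metrics behind the same interface.

The default fragment tolerance is 0.1 Th, configurable everywhere; it is a
common choice for this data type (precursor windows, in contrast, are
specified in ppm).

## Evaluation harnesses

**Alignment.** `alignment_benchmark()` scores labeled spectrum pairs,
labels them structurally similar when the Tanimoto coefficient of their
fingerprints exceeds 0.7 (strictly; the boundary rule and the threshold are
arguments), finds the cutoff maximizing the F-beta score over the sorted
unique scores plus a 0.01 grid (prediction rule: score ≥ cutoff, ties to
the lowest cutoff), tabulates the contingency table at that cutoff, and
computes the Kullback–Leibler divergence between the score and Tanimoto
distributions. KL is computed as KL(scores ‖ Tanimoto) on 20 equal bins
over $[0,1]$ with $10^{-10}$ add-epsilon smoothing; direction, binning and
smoothing are exposed because different conventions exist.

**Library search.** `library_search()` restricts candidates to a precursor
window of ± ppm · precursor/10⁶, scores them with any metric/scheme
combination, ranks by descending score (ties: smaller precursor deviation,
then identifier) and flags true positives by equality of the first 14
InChIKey characters. `precision_at_k()` averages over *all* queries —
a query with no candidates counts as precision zero rather than being
dropped, because silent queries are part of the evaluation — and
`auc_roc()` is the rank-based (Mann–Whitney, midrank ties) AUC.

## The synthetic benchmark

Real benchmark corpora for this task are licensed or large, so the package
ships a seeded generator whose output has the statistical structure the
evaluations need. Design choices, and what they do and do not emulate:

* **Templates.** Each synthetic molecule has 8–40 fragment m/z values on
  an integer grid plus a per-molecule decimal offset (pairwise separation
  far above twice the matching tolerance), a precursor in 300–900 Th, and
  log-normal ($\mu = 0, \sigma = 1$) max-normalized base intensities —
  the long-tailed low-intensity population that weighting targets.
* **Fingerprints.** One bit per fragment substructure (derived from the
  0.1-Th mass key; 8192 bits so keys never fold), which makes fingerprint
  Tanimoto track fragment-set overlap by construction. This identification
  of structural similarity with fragment sharing is the modeling choice
  that makes Tanimoto-versus-spectral-similarity evaluation meaningful
  without real chemistry.
* **Replicates** jitter m/z (sd 0.01 Th, below half the tolerance so true
  matches survive), multiply intensities by log-normal noise (sd 0.3), and
  lose fragments with probability $0.1 \cdot (1 - I/I_{\max})$ — a
  detection-limit model under which weak peaks drop out but the base peak
  never does, keeping replicates of one molecule recognizably similar.
* **Analogs** retain a fraction of fragments and shift the rest, plus the
  precursor, by a constant neutral loss. Retention is intensity-biased
  (probability proportional to base intensity): the shared core scaffold
  produces the major fragments, while modifications mostly relocate minor
  ones. A shifted fragment keeps its substructure bit with probability
  $q/(1+q)$, calibrated so the expected parent–analog Tanimoto equals the
  retained fraction $q$. Shifted fragments landing within twice the
  tolerance of a retained one are dropped to preserve peak separation.
* **Benchmark pairs** put a template against a *two-step* analog (an
  analog of an analog with independent overlaps and shifts drawn from a
  small pool of common neutral losses). A single constant-shift analog
  matches its parent completely under modified cosine — every fragment is
  either direct- or shift-matched — so one-step pairs cannot separate
  structural similarity levels at all; with two steps, only fragments kept
  twice (direct) or shifted twice (via the summed precursor difference)
  match, giving a continuous range of matched fractions aligned with the
  Tanimoto coefficient. 30% of pairs are unrelated template pairs,
  reflecting that random molecule pairs are mostly dissimilar. A quarter
  of pairs form the dominant-peak stratum: a fragment shared by both
  spectra is boosted to 80% of total intensity, reproducing the regime
  (few peaks, one aligned dominant peak) in which weighting lowers the
  score of genuinely similar pairs.
* **Dominance is molecule-level:** whether a template yields dominant
  spectra is a per-template coin, so its replicates agree.

What the generator does **not** emulate: physically realistic
fragmentation (bond energies, isotopes, adducts, charge states),
instrument-specific noise, collision-energy dependence, or real structural
chemistry. Passing the synthetic direction checks therefore shows that the
implementation behaves as the method intends under the stated statistical
structure — not that the same effect sizes would be observed on any
particular real corpus.

## Numerical and degenerate-input choices

* Duplicate m/z values within one spectrum are merged (intensities summed)
  at construction, so matching always sees strictly increasing m/z.
* Classic (raw-intensity) schemes are deliberately not scale-invariant, as
  in their original formulations; metrics renormalize, so the absolute
  scale never leaks into scores.
* Filtering order is fixed: precursor exclusion, relative-intensity floor,
  minimum peak count, precursor requirement; rejection is a return value
  (`NULL`), not an error. The shipped defaults (1.5 Th exclusion, 0.001
  relative floor, minimum 5 peaks) mimic common preprocessing for public
  MS/MS benchmark sets and are all configurable.
* Weighting is applied after filtering; both steps are explicit function
  calls, so the opposite order is available by composing them the other
  way.
* All-zero fingerprint pairs define Tanimoto 1 (with a warning); all-zero
  intensity spectra cannot be normalized or weighted (error).
* Cutoff optimization uses the candidate grid of observed scores plus a
  0.01-step lattice; ties resolve to the lowest cutoff so reported cutoffs
  are conservative.

## Problem sizes

The shipped evaluation and test sizes are chosen to estimate directions
and rates stably at desk scale: 200 templates, 2,000 alignment pairs and
500 search queries for the end-to-end benchmarks; 1,000-case fixtures for
the matching and ranking oracles. `scripts/acceptance.R` recomputes the
headline quantities from scratch at exactly these sizes for any seed.

## Known limitations

* The frequency table is unconditional on precursor mass and collision
  energy; both refinements are plausible but out of scope.
* Greedy matching is order-2 in peak counts per pair and can (rarely)
  miss the optimal assignment; the optimal assignment is kept as a test
  oracle, not offered as a production path.
* Fidelity/Bhattacharya-1 normalization to a $[0,1]$ similarity follows
  one common convention; other benchmarks rescale distances differently,
  which changes absolute values but not rankings.
* Entropy-similarity's half-weight treatment of unmatched peaks follows
  the merged-spectrum convention; alternatives exist.
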