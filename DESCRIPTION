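Package: specweight
Title: Intensity Weighting and m/z-Frequency Weighting for MS/MS Spectral Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tandem mass spectrometry (MS/MS) spectral similarity with
    intensity-weighting preprocessing. Implements classic intensity/mass-power
    weighting schemes (Sokolow, Stein-Scott, Horai, Kim), entropy-conditional
    weighting, intensity binarization, and a frequency-aware scheme that rescales
    low-intensity peaks (fourth root of the max-normalized intensity) and
    multiplies by the relative occurrence frequency of the peak's m/z value in a
    reference library, binned at 0.1 Da. Provides tolerance-based peak matching
    (direct and precursor-shifted), cosine, modified cosine, spectral entropy,
    fidelity and Bhattacharya-1 similarities with a pluggable metric registry,
    MGF and MSP readers and writers, and two evaluation harnesses: spectral
    alignment against structural (Tanimoto) similarity with F-beta cutoff
    optimization, contingency tables and Kullback-Leibler divergence, and
    ppm-windowed spectral library search scored by precision at K and AUC-ROC.
    A seeded synthetic-spectrum generator produces analog pairs, fingerprints
    and libraries so every harness runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
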