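Package: cuckooEEG
Title: EEG Channel Selection by Multiobjective Binary Cuckoo Search with
    KNN Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper channel selection for EEG-based biometric person
    identification. Candidate channel subsets are scored by k-nearest-neighbour
    identification accuracy under stratified 10-fold cross-validation combined
    with a channel-reduction term in a weighted-sum multiobjective fitness,
    and the subset space is searched by a binary cuckoo search metaheuristic
    (Levy-flight global walk, abandonment local walk, sigmoid transfer
    binarization, elitism). Includes the autoregressive feature pipeline
    (zero-phase band-pass and notch filtering, wavelet denoising, Burg or
    Yule-Walker AR coefficients per electrode), a planted-channel synthetic
    data generator for ground-truth validation, an exhaustive-enumeration
    oracle, a matched-budget random-search baseline, multi-run experiment
    drivers, and Wilcoxon signed-rank plus rank-summation comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
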