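Package: olfosc
Title: Oscillatory Analysis of Olfactory Bulb-Piriform Cortex Source Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-region source-level electrophysiological
    recordings of the human olfactory system. Provides superlet time-frequency
    decomposition, mass-univariate linear mixed-effects maps with weighted
    cluster-mass permutation correction, coherence spectrograms, nonparametric
    spectral Granger causality via Wilson spectral matrix factorization,
    searchlight support-vector-machine decoding of coherence spectrograms,
    Tort phase-amplitude coupling, and single-trial oscillatory burst
    detection, together with a synthetic source-level data generator that
    injects known effects so every stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    signal,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
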