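Package: resteeg
Title: Pre/Post Resting-State EEG Band Power, Coherence, Entropy and
    Phase-Amplitude Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired pre/post-intervention resting-state EEG
    recordings from the 10/20 montage. Implements the full feature pipeline:
    average-reference and zero-phase high-pass/notch filtering, amplitude-based
    artifact segment selection, Welch power spectra and region band power,
    region-pair magnitude-squared coherence, a binned-variance Tsallis-entropy
    estimator averaged over 100 interval lengths, and Canolty modulation-index
    comodulograms between slow-phase (1-10 Hz) and fast-amplitude (20-85 Hz)
    bands. Group-level pre/post comparison uses the paired Wilcoxon signed-rank
    test with normal-approximation Z and effect size r = Z/sqrt(n). A seeded
    synthetic EEG cohort generator (1/f background, region oscillations,
    phase-amplitude coupling, plantable pre-to-post effects) makes every stage
    testable without patient data. Minimal EDF and delimited-text readers and
    writers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
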