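Package: voicePD
Title: Dysphonia-Based Parkinson's Disease Screening with Discriminant
    Reduction and Genetically Optimized Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating voice-based Parkinson's
    disease classifiers from sustained-phonation acoustic features
    (jitter, shimmer, harmonicity, pitch, pulse and voicing measures).
    Implements Fisher linear discriminant reduction from first
    principles, a small feed-forward neural classifier trained by
    cross-entropy minimisation (quasi-Newton or adaptive-moment), a
    genetic algorithm over network architectures with leave-one-subject-out
    (LOSO) fitness, subject-aware cross-validation with confusion-matrix
    metrics including the Matthews correlation coefficient, and a
    class-conditional Gaussian simulator that emulates the cohort
    structure of multi-phonation clinical voice databases for
    ground-truth recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
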