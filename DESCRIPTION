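Package: apneaformer
Title: Transformer-Based Per-Second Sleep Apnea Detection from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects obstructive sleep apnea events from single-lead
    electrocardiogram recordings at one-second resolution using a transformer
    encoder classifier with interchangeable positional-encoding strategies:
    none, naive (normalized index), fixed sinusoidal, and a learnable
    content-aware encoding produced by a one-dimensional convolutional
    autoencoder with a transposed-convolution reconstruction layer. Includes a
    seeded synthetic cohort generator that emulates overnight polysomnography
    ECG structure (RR-interval modulation during apnea events, additive noise,
    missing samples, apnea-hypopnea-index severity mix and class imbalance),
    the full preprocessing chain (min-max normalization, missing-value
    imputation, non-overlapping 30-second windowing, per-second label
    projection), class-weighted AdamW training with a constant-then-decay
    learning-rate schedule, patient-level grouped splitting and k-fold
    cross-validation, and second-level plus event-level evaluation metrics.
    The neural network (attention, convolutions, layer normalization,
    backpropagation, optimizers) is implemented directly on R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
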