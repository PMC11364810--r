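Package: ctnet
Title: Convolutional Transformer Networks for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decoding of motor-imagery electroencephalography (EEG) trials with
    a compact convolutional-Transformer network (CTNet). The package provides
    an EEGNet-style convolutional feature extractor, a multi-head
    self-attention Transformer encoder, and a residual-fused classifier,
    together with per-trial Z-score standardization,
    segmentation-and-recombination data augmentation, subject-specific and
    leave-one-subject-out training protocols with validation-based model
    selection, and an evaluation suite (accuracy, Cohen's kappa, Hedges' g,
    exact paired Wilcoxon signed-rank test). A class-conditional synthetic
    motor-imagery EEG generator makes the whole pipeline testable without the
    BCI Competition IV recordings; an optional GDF loader supports the real
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
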