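Package: TriViewMIL
Title: Exam-Level Three-View Knee MRI Classification by Multi-Scale
    Attention Multiple-Instance Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exam-level multi-label classification of three-view
    (sagittal, coronal, axial) knee MRI studies. Implements a deterministic
    preprocessing pipeline (deduplication, validation, per-study z-score
    normalization, uniform slice sampling, resize/center-crop, consistent
    geometric augmentation), a multiple-instance-learning model family with
    a multi-scale attention slice aggregator and learned view fusion plus
    mean/max/gated-attention pooling baselines, a full training protocol
    (AdamW, cosine schedule with linear warmup, validation-based checkpoint
    selection, multi-seed runs with paired significance tests), an
    evaluation toolkit (macro AUROC, AUPRC, F1, Brier, robustness
    perturbations), a projected-gradient-descent solver for constrained
    performance planning, and a seedable synthetic exam generator in the
    MRNet directory layout so the entire pipeline is testable without any
    external download. Model gradients are computed by a small built-in
    reverse-mode automatic-differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
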