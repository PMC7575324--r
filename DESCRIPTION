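Package: locolearn
Title: Locomotor-State-Aware Quantification of Eyeblink Conditioning,
    Gait, and Split-Belt Adaptation in Head-Fixed and Freely Walking Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Behavioral quantification pipeline for cerebellum-dependent
    learning assays in mice. Converts eyelid videos to normalized
    eyelid-closure traces, classifies conditioned responses and builds
    learning curves with locomotor-state covariates (trial-level mixed
    models of response amplitude on walking speed, robust fits of learning
    onset on locomotor activity, stationary-trial analyses). Segments paw
    tracks into strides and computes the full individual-limb and interlimb
    gait-parameter suite, swing-trajectory alignment, variability
    (coefficients of variation) and a z-score/PCA/LDA discriminant mapping.
    Computes split-belt treadmill adaptation metrics (step-length asymmetry,
    initial error, change over split, aftereffects, percent adaptation,
    stance-speed compliance) with mixed-model genotype-by-phase contrasts.
    A synthetic-data module generates every input with known ground truth
    so the complete analysis is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    MASS,
    lme4,
    lmerTest,
    emmeans,
    signal,
    pracma,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
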