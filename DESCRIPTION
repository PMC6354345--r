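Package: lockbci
Title: EEG Analysis Toolkit for Mental-Imagery Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing and operating an endogenous, mental-imagery
    based brain-computer interface (BCI) from multichannel EEG. Implements
    the full offline/online analysis chain: auditory-oddball event-related
    potential assessment (mismatch negativity and P300 with moving-window
    paired t-tests and Bonferroni correction), event-related spectral
    perturbation maps with band topographies, a Riemannian-geometry
    classification framework operating on trial spatial covariance matrices
    (affine-invariant distance, Riemannian mean, tangent-space mapping,
    ANOVA variable screening, linear discriminant analysis), a conventional
    band-power/hemispheric-asymmetry framework with sequential floating
    forward feature selection, and evaluation protocols (leave-one-out
    cross-validation, simulated online runs, test-retest with stale and
    combined training sets, electrode-count curves, binomial chance-level
    bounds). A seeded synthetic-EEG module generates oddball and imagery
    sessions with configurable ERP components and band-power modulations so
    every stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
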