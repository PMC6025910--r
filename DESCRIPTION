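Package: chaosrvm
Title: Chaos-Kernel Relevance Vector Machines for Four-Class Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sparse Bayesian classification of four-class motor-imagery EEG
    with a chaos-derived kernel. Implements a binary relevance vector machine
    trained by Laplace-approximation hyperparameter re-estimation, a kernel
    family derived from the invariant density of the logistic map (plus
    Gaussian and polynomial baselines), two-class common spatial pattern
    (CSP) filtering with log-variance features, and a one-versus-one
    pipeline with majority voting, band-pass preprocessing, repeated
    stratified cross-validation and Cohen's kappa. A chaotic-dynamics module
    iterates the logistic map, estimates Lyapunov exponents and evaluates
    the invariant densities from which the kernel is derived, and a
    synthetic EEG generator plants class-specific spatial patterns so the
    whole stack is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
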