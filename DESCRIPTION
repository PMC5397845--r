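Package: nsplast
Title: Pattern Recognition Under Nonspecific Synaptic Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Storage and recall of sparse binary patterns in a linear
    associative unit whose synapses undergo multiplicative long-term
    depression (LTD) that may leak to neighboring synapses, as happens at
    cerebellar parallel-fibre to Purkinje-cell synapses when nitric oxide
    diffuses away from the active site.  Provides ring (1D exponential) and
    Euclidean (3D Gaussian) leakage kernels, a surrogate spiny-dendrite
    morphology generator with SWC/CSV import and export, kernel-matched
    local displacement and additive pattern noise, a signal-to-noise
    recognition statistic with its closed-form analytic counterpart,
    weight-conserving homeostatic potentiation factors, and seeded
    experiment drivers for noise, loading, sparsity and kernel-mismatch
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
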