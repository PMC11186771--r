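Package: stochclock
Title: Aging Clocks Built from Accumulating Stochastic Variation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and model-fitting tools for studying how epigenetic
    and transcriptomic aging clocks can arise from purely stochastic
    variation. Provides bulk simulators that accumulate normal-distributed
    noise on a bounded ground state (with clamped, unbounded, or logit-space
    dynamics), single-cell DNA-methylation simulators driven by per-site
    maintenance (E_m) and de novo (E_d) efficiencies including an event-based
    Gillespie variant, cross-validated elastic-net clock construction with
    invertible age transforms, transcriptome binarization and cell-type
    residual adjustment, and an evaluation suite (correlation metrics,
    permutation controls, parameter sweeps) for benchmarking the resulting
    clocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
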