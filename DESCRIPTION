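Package: effectinfo
Title: Effective Information and the Causal Plane for Feedforward Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Perturbation-based, information-theoretic analysis of the causal
    structure of small feedforward neural networks. Implements effective
    information (EI) of layer-to-layer connectivity under maximum-entropy
    interventions, its decomposition into sensitivity and degeneracy (the
    "causal plane"), the pairwise sum EI_parts, and feedforward integrated
    information (phi = EI - EI_parts), together with a deterministic
    quadrature oracle, single-edge EI curves and two-input EI manifolds, a
    minimal gradient-descent trainer with checkpointing, synthetic
    classification tasks, trajectory tracking across training, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    MASS,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
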