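Package: adnet
Title: Active Dendrites Networks for Multi-Task and Continual Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements point neurons augmented with active dendritic
    segments: each neuron computes a linear feedforward sum that is
    multiplicatively gated by a sigmoid of the strongest dendritic
    response to a task context vector, followed by a k-Winner-Take-All
    (kWTA) sparse activation and fixed sparse weight masks.  Provides
    prototype-based context inference (task-aware input-space means and
    a task-free online clustering variant driven by Hotelling's
    t-squared two-sample test), permuted-image continual-learning task
    streams (permutedMNIST from IDX files or a bundled synthetic
    generator), a sequential training harness with a dense MLP baseline,
    and analyses of the task-specific subnetworks that emerge after
    training (activation frequencies, dendritic response maps, overlap
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
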