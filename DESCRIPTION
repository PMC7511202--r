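Package: ipnet
Title: Intrinsic Plasticity and Incremental Normalisation for Deep Feedforward Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a local intrinsic-plasticity (IP) rule that adapts the
    gain and bias of tanh neurons from batch input/output statistics, together
    with the classic Infomax rule and an incremental variant of batch
    normalisation, as per-layer mechanisms inside a fully connected feedforward
    network trained with backpropagation and Adam. Provides analysis
    instruments for the information-maximisation interpretation of these
    rules: a histogram differential-entropy estimator on the tanh output
    support, fixed-distribution convergence experiments, layer-wise activation
    gradient probes for studying the vanishing-gradient problem, and a
    numerical equilibrium solver for the coupled gain/bias fixed point.
    Includes seeded generators for parametric scalar input streams and
    Gaussian-blob classification tasks, optional readers for MNIST (IDX) and
    CIFAR-10 (binary batch) files, and a command-line experiment harness with
    repetition averaging and tidy CSV/JSON outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
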