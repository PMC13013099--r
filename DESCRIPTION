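Package: contextsnn
Title: Context-Modulated Adaptive Spiking Neural Networks Under Weight Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of leaky integrate-and-fire (LIF) spiking
    neural networks whose firing threshold or membrane time constant is shifted
    by a learned per-unit parameter scaled by a global scalar context signal
    that tracks the level of synaptic-weight perturbation. Provides discrete-time
    LIF dynamics with SuperSpike surrogate gradients, Gaussian and dose-dependent
    (total-ionizing-dose) weight perturbation models with trial-frozen draws,
    feedforward and convolutional-recurrent network architectures trained by
    backpropagation through time, synthetic small-object-tracking and toy
    frame-classification tasks, train-by-test perturbation sweep grids, and
    latent-state PCA trajectory analysis, so that recovery of task performance
    by context-modulated adaptation can be studied end to end on a desk-scale
    CPU budget.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
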