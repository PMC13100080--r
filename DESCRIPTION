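Package: reservoirHH
Title: Hybrid Reservoir Computing for Model-Error Correction in Driven
    Hodgkin-Huxley Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a current-driven Hodgkin-Huxley neuron with
    tanh-parameterised gate kinetics, generates identifiability-oriented
    current protocols mixing Lorenz chaos with random current steps, and
    trains echo-state reservoirs -- stand-alone or coupled to a deliberately
    detuned surrogate Hodgkin-Huxley model -- to predict membrane voltage in
    closed loop and to reconstruct the unobserved ion-gate dynamics.  Six
    hybrid reservoir-model architectures are provided together with a
    windowed-RMSE benchmark harness for model-error sweeps, crossover
    detection and gate-recovery metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    deSolve,
    yaml,
    withr,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
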