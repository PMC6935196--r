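Package: mrnmem
Title: Memory and Bistability in Mutual Repression Networks with Negative
    Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of cellular memory in a
    three-protein mutual repression network (MRN) and its extension with
    negative autoregulation (MRN-NA). Provides the Hill-kinetics rate
    equations and their numerical integration, an exact Gillespie stochastic
    simulation of the corresponding birth-death processes, a quasi-steady-state
    one-variable reduction with Fokker-Planck stationary densities and
    stochastic potentials, mean first-passage times between the bistable
    steady states, and the parameter-sweep pipelines (memory regions,
    bistable regions, first-passage and noise comparisons) used to map where
    a transient inductive signal leaves a persistent expression state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
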