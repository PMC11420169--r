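Package: motorsteps
Title: Step Detection, Segmentation and Dwell-Time Kinetics for
    Single-Molecule Motor Trajectories
Version: 0.1.0
Authors@R:
    person("Motorsteps", "Developers", email = "motorsteps@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for nanometre-precision localization traces of
    processive cytoskeletal motors (e.g. dynein tracked by MINFLUX in live
    neurons): bias-free change-point step detection on 2D traces, motion-axis
    estimation and on/off-axis step decomposition, classification of traces
    into processive runs, pauses and direction reversals, discrete-time
    Markov-chain modelling of reversal mechanisms with stationary
    distributions, and left-truncated maximum-likelihood dwell-time fitting
    (single exponential, Erlang-2, hypoexponential) with Akaike-weight model
    selection.  A generative simulator of stepping traces, dwell-time samples
    and kymographs with full ground truth makes every stage testable without
    instrument data; a directional Fourier filter separates retrograde and
    anterograde components of kymographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
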