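Package: pqnsim
Title: Piecewise Quadratic Neuron Model Simulation and Hardware Arithmetic Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the Piecewise Quadratic Neuron (PQN) model family:
    two-, three-, four-variable and extended four-variable variants whose
    nullclines are piecewise quadratic with smoothness-constrained branch
    junctions. Provides forward Euler integration in a floating-point backend
    and a bit-exact fixed-point (Q-format) backend that emulates FPGA
    shifter/adder arithmetic, spike-train analysis tools (interspike-interval
    statistics, coefficient of variation and local variation, burst
    segmentation, phase-resetting and graded-response curves), and
    hardware-planning calculations (shift-add decomposition of constant
    coefficients, DSP tiling, real-time cycle budgets). Includes a command-line
    interface and JSON/CSV readers and writers for parameters, stimuli, traces
    and spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
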