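Package: qualnet
Title: Qualitative Network Modelling and In Silico Screening of Cell Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, simulate and analyse multi-level qualitative networks
    (generalised Boolean networks in which each node takes an integer level in a
    finite range and moves stepwise toward a target function of its regulators).
    Provides exact-arithmetic target-function evaluation with cross-range scaling,
    synchronous update semantics with exhaustive attractor enumeration, sound
    interval-refinement bounds on stable states of large networks, in silico
    mutation and drug screening across genetic backgrounds (including pairwise
    combination screens, tumour growth scores and selection of optimal drug
    combinations), scoring of model predictions against experiment tables, BMA-style
    JSON and tabular model interchange, and synthetic network/experiment generators
    for property-based testing. Ships a synthetic reduced melanoma-Langerhans-cell
    signalling model demonstrating bistability of an autocrine TNF-alpha positive
    feedback loop.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
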