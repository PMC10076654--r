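Package: rasim
Title: Dual-Learning Columnar Cortex Simulation with a Basal-Ganglia
    Recommendation Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a biologically inspired categorical learning model in
    which a columnar three-layer spiking cortex is trained only by
    temporal-correlation (Hebbian) plasticity with reversal, contribution-miss
    depression and homeostatic scaling, and is read out by a basal-ganglia
    layer of per-category recommendation weights trained only by consequence
    feedback (teacher signal or bare correct/incorrect).  Includes a generator
    for never-identical categorical stimuli (propensity profiles, a
    1-in-10,000 chance draw and 40 Hz gamma-interleaved working-memory
    triples), hippocampal co-activation grouping used to bias initial cortical
    wiring, and orchestration of a novelty-learning experiment and a
    split-training interference/recovery experiment with top-k accuracy and
    set-balance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
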