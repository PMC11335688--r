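Package: striatnet
Title: Biophysical Striatal Network Simulation and Equation-Free Bifurcation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a large-scale biophysical model of the striatum built
    from modified Hodgkin-Huxley medium spiny neurons and fast-spiking
    interneurons coupled by GABAergic synapses on a spatially embedded
    small-world graph. Provides an equation-free toolbox (restriction,
    lifting, coarse timestepper) that reconstructs the macroscopic drift of
    the mean synaptic activity, locates its fixed points with stability, and
    traces the saddle-node bifurcation in the cortico-striatal activation
    current. Includes a deep-brain-stimulation module with spatially decaying
    pulsed currents and a closed-loop proportional amplitude controller.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
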