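Package: granlayer
Title: Parametric Reconstruction and Simulation of the Cerebellar Granular Layer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to reconstruct the cerebellar granular layer in a 3D volume
    (Golgi cell, granule cell and glomerulus placement, six connection matrices
    built from convergence/divergence rules, and mossy-fiber rosette clustering)
    and to simulate its activity with conductance-based Hodgkin-Huxley neuron
    models, kinetic AMPA/NMDA/GABA receptor synapses and Golgi-Golgi gap
    junctions. Includes stimulation protocols (background and burst mossy-fiber
    input, center-surround mapping), connection statistics, spike rasters, and
    analytic memory-occupancy estimators for design and simulation stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
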