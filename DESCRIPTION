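Package: atrialRD
Title: Arrhythmogenicity of Fibrotic Atrial Substrate by Monodomain
    Simulation and Reentrant-Driver Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico assessment of the arrhythmogenic capacity of
    fibrotic left-atrial substrate. Implements a human atrial action-potential
    model with atrial-fibrillation and fibrotic ionic remodeling variants, a
    monodomain reaction-diffusion solver on cables, sheets and bilayer
    triangulated surfaces with fibrosis-dependent anisotropic conductivities,
    synthetic fibrotic-substrate generation, a clinical rapid-pacing
    arrhythmia-induction protocol, phase-based reentrant-driver detection with
    region-wise inducibility scoring, local fibrosis density/entropy mapping
    with pro-reentry classification, and virtual-cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
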