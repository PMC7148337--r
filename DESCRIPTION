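Package: gemrecon
Title: Orthology-Based Reconstruction and Interrogation of Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for orthology-based reconstruction of genome-scale
    metabolic (GSM) models from a reference model: translation of
    gene-protein-reaction (GPR) Boolean rules through an orthology map,
    triage of reactions lacking target-organism gene support, assembly of
    minimal (gap-filled) and maximal draft models, flux balance and flux
    variability analysis on a built-in linear-programming core, functional
    validation via metabolite-conversion and reaction-optimization tests,
    microarray present/absent call processing with iterative correlation
    z-score sample QC, tissue-specific model extraction by an
    mCADRE-style pruning algorithm with a biomass-production guard, and
    single-gene essentiality prediction by FBA and linear MOMA with
    confusion-matrix evaluation against knockout screens. Includes
    synthetic-data generators producing flux-consistent toy models,
    orthology maps, expression calls and brute-force ground truth so the
    whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
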