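Package: morphotree
Title: Phylogenetic Inference from 3D Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating phylogenies from geometric morphometric
    landmark data, built around the turtle-shell (carapace and plastron) study
    design. Implements the full landmark processing pipeline (TPS input,
    replicate consensus, abnormality repair by reflection, generalised
    Procrustes superposition, symmetrisation, species consensus, plastral lobe
    splitting and dataset assembly), five native tree optimality criteria with
    heuristic searches (landmark analysis under parsimony with nested spatial
    grids, linear parsimony, unweighted squared-change parsimony, maximum
    likelihood under Brownian motion, and neighbour joining on Procrustes
    distances), landmark resampling and bootstrap consensus support,
    quartet and split tree dissimilarities with a topological-accuracy
    statistic and tree-space visualisation, leave-one-out placement of single
    species on a molecular scaffold, and a synthetic Brownian-motion study
    generator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    cluster,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
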