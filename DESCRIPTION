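Package: vorbind
Title: Voronoi Structural Neighboring Properties for Protein-Protein
    Binding Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein binding sites from the structural
    neighboring property of surface residues. Heavy atoms are tessellated
    with a weighted Voronoi (power/Laguerre) diagram to obtain per-residue
    contact, solvent-exposed and total polyhedral face areas; these weight
    physicochemical residue features (hydrophobicity, charge, hydrogen-bond
    capacity) into a neighborhood-aware property. Univariate and bivariate
    normal models of the property across known interfaces yield a log-odds
    pair energy; thresholding, a distance-weighted neighborhood update and
    graph clustering produce predicted interface patches. Also included: a
    linear docking-pose scorer built on the same statistics, CAPRI-style
    evaluation (fraction of native contacts, interface RMSD, binding-site
    P-value), deterministic synthetic-structure generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
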