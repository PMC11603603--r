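Package: nohcg
Title: No-Hydrogen Coarse-Grained Potentials by Variational Force Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for bottom-up coarse-grained (CG) modelling of
    proteins at heavy-atom resolution. Implements the no-hydrogen (noh)
    coarse-graining map with basic force aggregation and a 12-class
    (element, bonded-hydrogen count) bead embedding; curation of
    coordinate-force datasets (domain filters, temperature pooling,
    stride and train/validation/test splitting); a strictly invariant
    radial-basis pair potential trained by variational force matching
    with analytic gradients; a BAOAB Langevin dynamics engine operating
    on the aggregated bead masses; and thermodynamic-consistency
    analysis through time-lagged independent component analysis (TICA),
    K-means microstate discretization, reversible Markov state models
    and free-energy surfaces. Synthetic toy systems with closed-form
    all-atom force fields and analytic coarse-grained potentials of
    mean force allow the full pipeline to be exercised and validated
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
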