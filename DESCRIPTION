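Package: cloneCA
Title: Lattice Cellular-Automaton Simulation of Clonal Diversification in
    Clear-Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained three-dimensional cellular-automaton model of
    clear-cell renal cell carcinoma (ccRCC) growth and clonal evolution.
    Tumour voxels (1 mm^3 units) on a cubic lattice stochastically die,
    proliferate under Surface or Volume growth rules, and acquire driver
    events from a 26-event ccRCC panel under saturated or additive selective
    advantage models, optionally with depth-dependent central necrosis.
    Includes clone bookkeeping (cancer cell fractions, Shannon diversity),
    spatial analyses of two-dimensional tumour slices (microdiversity hotspot
    mapping, bootstrap power-law gradient fitting, contour circularity,
    fitness gradients, youngest subclones, regional biopsies), time-course
    and evolutionary-replay analyses, and a cohort interface for
    patient-style multi-region tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
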