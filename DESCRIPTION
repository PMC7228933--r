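Package: memsaxs
Title: Automated SEC-SAXS Analysis and Modeling of Membrane-Protein-Detergent Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for small-angle X-ray scattering (SAXS) data
    from membrane proteins solubilized in detergent, measured with inline
    size-exclusion chromatography (SEC-SAXS). Processes raw 1D frame series
    into buffer-subtracted scattering curves with a quantitative figure-of-merit
    K for data quality, computes model-free invariants (Guinier radius of
    gyration, pair-distance distribution and maximum dimension, Porod volume,
    apparent molecular weight), and reconstructs low-resolution models of the
    protein-detergent complex along three paths selected from available a
    priori information: hybrid fitting of a toroidal detergent corona around an
    atomic model, constrained three-phase ab initio bead modeling on a
    cylinder-plus-hemi-tori search grid, and single-phase ab initio shape
    reconstruction with multi-run consensus averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    signal,
    bio3d,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
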