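Package: covcontact
Title: Covariance-Based Detection of Attractive and Repulsive
    Protein-Protein Interface Interactions from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing workflow for molecular dynamics trajectories
    of protein-protein complexes. Builds the interprotein C-alpha
    covariance matrix and its normalization (cross-correlation), applies
    sign-dependent spatial cutoffs to obtain a close-contact covariance
    matrix, and classifies each surviving residue pair per frame into
    attractive (salt bridge, hydrogen bond, hydrophobic) and repulsive
    (like-charge, hydrophobic-polar) interaction types with percentage
    occupancies. Includes a static-structure distance prefilter, a
    brute-force all-pairs scanner used as a correctness oracle, synthetic
    trajectory generators with known covariance structure, and exporters
    for labeled matrices, viewer scripts and B-factor-annotated
    structures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
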