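Package: PerturbANM
Title: Anisotropic Network Models with Linear-Response Perturbation and
    Contact Switch-Off Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained mechanical analysis of ligand- and
    voltage-modulated conformational change in (pseudo-)symmetric protein
    oligomers. Builds an anisotropic network model (ANM) from C-alpha
    coordinates, computes its normal-mode spectrum and Moore-Penrose
    mechanical covariance, applies binding-pocket or field-mimicking
    forces under linear response theory, decomposes the response into
    soft non-degenerate modes, and screens every symmetric contact class
    by switching its springs off and measuring the change in the
    displacement field. Includes a generator of exactly C4-symmetric
    toy tetramers so the full pipeline is testable without external
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Network, Proteomics
RoxygenNote: 7.3.3
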