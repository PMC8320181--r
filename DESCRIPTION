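Package: confcover
Title: Conformer Ensemble Coverage Analysis in Ring-Torsion Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing conformer ensembles of macrocycles in the
    continuous sin/cos embedding of their ring dihedral angles. Builds PCA
    torsion maps from a reference ensemble, projects other ensembles onto
    them, and quantifies how completely one ensemble covers another via
    k-means cluster mixing, total/generalized variance curves, and a
    Mahalanobis-distance coverage metric with an accompanying permutation
    test for homogeneity of multivariate dispersion. Also computes
    conformer-level descriptors (intramolecular hydrogen bonds, 3D polar
    surface area, relative-energy bins) for map color-coding, and ships a
    von Mises mixture simulator of multi-basin torsional ensembles for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    ChemmineR,
    bio3d,
    vegan,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
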