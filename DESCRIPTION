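Package: molinverse
Title: Inverse Property-to-Structure Mapping for Small Organic Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns an approximate inverse mapping from global quantum-mechanical
    properties to three-dimensional molecular structures of small organic
    molecules. Molecules are represented as padded, canonically ordered Coulomb
    matrices, which are exactly invertible (composition from the diagonal,
    geometry by classical multidimensional scaling) up to chirality. A
    variational auto-encoder over the Coulomb-matrix vectors is trained jointly
    with a property encoder so that structures and property vectors share a
    common latent representation; the property encoder composed with the
    decoder then maps a property vector to a structure. On top of the mapping
    the package provides gradient attribution maps over properties, targeted
    conditional generation through a BIC-selected Gaussian mixture model of the
    property space with a latent self-consistency filter, geodesic
    interpolation of transition geometries between conformational isomers, and
    a synthetic molecule/property generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
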