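Package: epimech
Title: Mechanical Status of Epithelial Monolayers from Images, Indentation
    and Traction Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the mechanical state of epithelial monolayers such
    as the retinal pigment epithelium. Converts segmentation label masks
    into filtered cell tessellations with per-cell morphometrics (area,
    perimeter, shape index, elongation) and neighbor topology, and computes
    monolayer-scale statistics: rescaled-area distributions, Lewis' and
    Desch's laws, and the Aboav-Weaire relation with cell-count-weighted
    pooling across animals. Fits force-indentation curves with the Hertz
    contact model under two protocols (extracellular-matrix atomic force
    microscopy with linear background subtraction, and cell-monolayer
    nanoindentation with a fixed depth window and goodness-of-fit gate).
    Reconstructs substrate traction from bead displacement fields by
    regularized Fourier-transform traction cytometry and intercellular
    stress by a two-dimensional force balance. Provides image-derived
    functional metrics (phagocytosis efficiency, proliferation ratio,
    radial region binning with per-eye intensity normalization) and a
    synthetic-data generator with known ground truth for every input, so
    the whole pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Matrix,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
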