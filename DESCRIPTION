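Package: opentoplsm
Title: Simulation and Reconstruction for Open-Top Bessel-Beam Two-Photon
    Light-Sheet Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale simulator and reconstruction toolkit for open-top
    two-photon light-sheet microscopy with Bessel-beam illumination. Models
    the axicon-generated Bessel-Gauss excitation sheet by scalar diffraction,
    generates seeded synthetic specimens (bead grids, layered skin, pancreatic
    ducts, prostate glands), simulates oblique 45-degree strip acquisition with
    depth-dependent attenuation and camera noise, and implements the inverse
    pipeline: deskew into world coordinates, mosaic stitching, resolution and
    imaging-depth metrology, acquisition time and data budgets, patch
    preparation for style-transfer training, and a deterministic Beer-Lambert
    virtual H&E renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
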