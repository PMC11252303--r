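Package: helixline
Title: Layer-Line Analysis and Helical Reconstruction of Filaments in
    Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for identifying and characterising helical
    actin filaments inside microtubules from cryo-electron tomography style
    density volumes. Generates synthetic pseudo-atomic filaments and
    microtubules with specified helical symmetry and tomographic noise,
    measures crossover spacing, genetic pitch and axial rise from layer
    lines in power spectra of projected filaments, classifies filaments as
    short-crossover (cofilin-decorated) or canonical F-actin, performs
    real-space helical reconstruction by rotate-and-shift averaging, fits
    atomic models into maps with a normalized cross-correlation score,
    counts microtubule protofilaments by rotational symmetry scanning, and
    quantifies lumen occupancy and incidence statistics. Reads and writes
    MRC2014 volumes, PDB coordinates and CSV annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
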