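Package: boltzlie
Title: Iterative Boltzmann-Weighted Linear Interaction Energy Models for
    Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and prediction of protein-ligand binding free
    energies with the iterative Linear Interaction Energy (LIE) method, in
    which ensemble-average ligand-surrounding interaction energies from
    multiple molecular dynamics simulations (different protein templates
    and ligand binding poses) are combined into one free energy through
    self-consistent Boltzmann weighting. Includes Cheng-Prusoff conversion
    of IC50 inhibition data to binding free energies, nearest-neighbor
    clustering of docked ligand poses with central-structure selection and
    an active-site filter, exhaustive train/test split scanning for model
    assessment, a principal-axes applicability-domain check, and a
    synthetic-data generator with known ground truth for validation. Ships
    a 17-compound aryloxypropanolamine CYP 2D6 inhibition dataset as a
    packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
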