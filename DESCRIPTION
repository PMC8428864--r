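Package: psiexciton
Title: Excitonic Couplings and Qy Absorption Modelling for Photosystem I Chlorophylls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connecting pigment geometry in photosystem I (PSI) to
    its Qy absorption spectroscopy. Computes chlorophyll transition dipoles and
    pairwise excitonic couplings from atomic coordinates with the
    transition-charge (TrESP) method, assembles and diagonalizes Frenkel
    exciton Hamiltonians, and simulates disorder-averaged absorption spectra by
    Monte-Carlo sampling of site energies. Also implements the matching
    experimental workup (area normalization, difference spectra, multi-Gaussian
    band deconvolution, peak and ratio features), residue-conservation
    tabulation on protein alignments, and seed-deterministic synthetic-data
    generators (idealized chlorin geometries, charge sets, Gaussian-mixture
    spectra, toy alignments) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
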