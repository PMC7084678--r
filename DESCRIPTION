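Package: lamellar
Title: Lamellar Neutron Diffraction Analysis of Oriented Lipid Multilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduction and analysis of one-dimensional neutron diffraction
    data from stacked (lamellar) lipid bilayers. Reads 1D diffractograms,
    subtracts smooth backgrounds, fits and indexes Bragg peaks onto lamellar,
    hexagonal, or coexisting lamellar lattices, converts integrated
    intensities to structure-factor amplitudes with the Lorentz correction
    for oriented samples, resolves structure-factor signs by D2O
    contrast-variation linearity, reconstructs the neutron scattering length
    density profile across the bilayer by Fourier synthesis, and extracts
    Luzzati bilayer parameters (bilayer thickness, hydrophobic thickness,
    water layer thickness, area per lipid, waters per lipid) with propagated
    uncertainties. Includes a parametric forward model of a centrosymmetric
    bilayer unit cell that generates realistic synthetic diffractograms and
    contrast series for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
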