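Package: nanomech
Title: Micromechanical Prediction of Nanofibrous Membrane Tensile Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric micromechanical model for the uniaxial stress-strain
    response of randomly oriented electrospun nanofibrous membranes. Fits the
    logarithmic single-fiber constitutive law sigma = a - b*ln(eps + c) to
    measured single-nanofiber tensile curves, applies affine reorientation
    kinematics to the in-plane fiber orientation distribution, averages the
    diameter-corrected axial fiber forces by Gauss-Legendre quadrature over
    orientation, and scales to membrane stress through porosity and the
    harmonic mean fiber diameter. Includes an independent discrete-fiber
    Monte-Carlo simulator used as a cross-check oracle, synthetic-data
    generators for single-fiber curves and diameter samples, CSV/YAML I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
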