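Package: afmlattice
Title: Lattice-Quality Analysis of DNA Origami Monolayers from High-Speed AFM Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying surface-assisted self-assembly of DNA
    origami triangles on mica from time-resolved atomic force microscopy
    height images. Reads calibrated frame stacks, flattens scan lines,
    segments triangular particles and tracks surface coverage, computes the
    Delaunay-angle order parameter n(Theta60) (interior angles within 60
    degrees +/- 5 degrees per square micrometre), fits pseudo-first-order
    adsorption kinetics with extra-sum-of-squares model comparison, and
    scores long-range hexagonal order from the 2D Fourier magnitude
    spectrum. Includes a synthetic scene generator and a random sequential
    adsorption simulator with injection lag that provide ground truth for
    validating every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    graphics,
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
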