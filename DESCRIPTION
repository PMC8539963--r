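Package: anisograd
Title: Variational Anisotropic Gradient-Domain Image Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gradient-domain image processing with anisotropic diffusion.
    An image is edited by modifying its gradient field and reintegrating the
    result by evolving a diffusion partial differential equation. Alongside
    the classical Poisson (gradient-descent) reintegration and the ad hoc
    anisotropic variant driven by the structure tensor of the evolving image,
    the package implements the variational formulation in which the diffusion
    tensor is assembled from the eigenstructure of the difference structure
    tensor, i.e. the structure tensor of the residual between the evolving
    gradient and the target field. A catalogue of edge-stopping potentials
    (Perona-Malik, total variation, linear) is provided, together with
    application front-ends for linear and gamma local contrast enhancement
    and colour-image daltonisation, seeded synthetic test fixtures, PNG/PPM
    input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
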