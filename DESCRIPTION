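Package: fluorscan
Title: Forward Simulation of Full-Field and Scanning Fluorescence Imaging
    in Diffuse Slab Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Continuous-wave diffusion forward model for planar fluorescence
    imaging of deep tissue.  Simulates excitation and emission light transport
    through a slab phantom containing cylindrical fluorescent targets, for two
    virtual instruments: a full-field illumination system imaged on a camera
    plane, and a point-scanning system with an integrating disc detector.
    Includes a fast coupling-factor method that renders a full raster scan
    from a single pair of diffusion solves, spectral models of tissue
    absorption and reduced scattering, an autofluorescence background model,
    and profile/FWHM/Sparrow-criterion resolution analysis with tidy outputs
    and ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
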