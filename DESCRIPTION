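Package: conefund
Title: Continuous Cone Spectral Sensitivities for Standard and Individual Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates human L-, M- and S-cone corneal spectral sensitivities
    (cone fundamentals) as continuous functions of wavelength from closed-form
    Fourier-polynomial templates of the photopigment absorbance spectra and of
    the macular and lens pigment density spectra. Supports the standard 2-deg
    and 10-deg observers as well as individualized observers with altered
    photopigment, macular and lens optical densities, spectrally shifted
    photopigments (including shifts derived from L/M opsin genotypes and the
    ser180/ala180 L-cone polymorphism), tristimulus integration, chromaticity
    coordinates, and exact linear transformations into Stiles-Burch RGB and
    CIE XYZ colour-matching spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
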