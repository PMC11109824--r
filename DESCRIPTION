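Package: ampscatter
Title: Membrane Biophysics of Antimicrobial Peptides from X-Ray and
    Neutron Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for membrane-active antimicrobial
    peptides studied by scattering and spectroscopy: peptide
    physicochemical descriptors and MIC panel statistics, circular
    dichroism secondary-structure decomposition, diffuse low-angle X-ray
    scattering fits of the bilayer bending modulus under smectic
    liquid-crystal theory, wide-angle chain order parameters from a
    tilted-rod model, scattering-density-profile electron density and
    form-factor fitting with peptide localization, lamellar Bragg and
    Scherrer analysis of vesicle fusion in solution SAXS, and
    composition-space modeling of specular neutron reflectivity from
    tethered bilayers. Seeded synthetic-data generators provide ground
    truth for every modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
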