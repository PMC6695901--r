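Package: mucofilm
Title: Scattering and Surface-Sensing Analysis of Mucin Layers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and fits the measurements used to characterise mucin in
    bulk solution and as thin films at interfaces: small-angle X-ray
    scattering form factors (Gaussian coil, dumbbell peptide-plus-globule
    with a Percus-Yevick hard-sphere structure factor), Guinier and
    fractal power-law analysis, quartz crystal microbalance with
    dissipation (Sauerbrey mass and thickness), and specular neutron
    reflectometry slab models computed by the optical matrix method with
    Nevot-Croce roughness, resolution smearing and simultaneous
    multi-contrast co-refinement with labile-hydrogen exchange. Includes
    deterministic synthetic-data generators for every stage so the whole
    pipeline can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
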