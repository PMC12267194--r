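Package: aortaflow
Title: Statistical Shape Modeling and Reduced-Order Hemodynamics of the
    Thoracic Aorta Under VA-ECMO
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Generates point-corresponded synthetic thoracic-aorta
    populations, fits principal-component statistical shape models and
    augments them by mode/standard-deviation sweeps, extracts centerline
    morphometrics (length, tortuosity, inscribed radius, curvature,
    torsion) over the seven characteristic tracts, and simulates healthy,
    cardiogenic-shock and VA-ECMO-supported blood flow on a lumped
    vascular network with three-element Windkessel outlets,
    one-dimensional transport of the ECMO blood fraction along the aorta,
    and localization of the native/ECMO watershed (mixing) zone.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
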