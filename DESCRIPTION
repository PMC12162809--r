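Package: tehvsim
Title: Mechano-Mediated Remodeling of Tissue-Engineered Heart Valves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric leaflet geometry generation, a fiber-level
    stress-fiber/collagen remodeling constitutive model, quasi-static
    nonlinear finite-element mechanics of pressure-loaded leaflets with
    frictionless contact, and design-evaluation metrics (regurgitant
    orifice area, stress concentrations, fiber order parameter, cost
    function) for ranking tissue-engineered heart valve designs under
    pulmonary and aortic diastolic loading.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
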