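Package: femfri
Title: Strain-Energy Fracture Risk Index from Finite Element Models of the
    Proximal Femur
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-CT style finite element assessment of hip fracture
    risk. Generates synthetic proximal-femur tetrahedral phantoms with
    Hounsfield-unit fields, maps HU to ash density, Young's modulus and yield
    stress through empirical power laws, solves the inhomogeneous linear
    elastostatic problem under single-leg stance and sideways-fall load cases
    with 4-node tetrahedra, identifies the femoral neck and shaft axes and the
    three clinically critical cross-sections, and evaluates the strain-energy
    fracture risk index (the ratio of load-induced to yield strain energy over
    a cross-section) by triangle Gaussian quadrature.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
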