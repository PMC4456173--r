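Package: bmpheal
Title: Mechano-Chemical Simulation of BMP-2 Mediated Bone Defect Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional mechano-chemical simulator of bone defect
    healing in the rat femur. Couples reaction-diffusion-chemotaxis dynamics
    of bone morphogenetic protein 2 (BMP-2) delivered from a degrading
    alginate hydrogel with a mechanoregulated tissue-differentiation model:
    dose-dependent modulation curves for proliferation, chemotaxis,
    chondrocyte hypertrophy and bone-matrix production scale the rates of a
    strain-driven cell-fate algorithm evaluated on a plane-strain finite
    element model of the fixated femur. Reproduces healing of a regular
    2 mm fracture gap and the dose-dependent bridging versus non-union
    behaviour of an 8 mm critical-size defect treated with BMP-2 loaded
    hydrogel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
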